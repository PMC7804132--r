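name	target_node	action	bbb	safety	bbb_waiver	original_indication	note
Flibanserin	PTEN	inhibit	permeable	ok	FALSE	hypoactive sexual desire disorder	
Everolimus	mTORC1	inhibit	permeable	ok	FALSE	immunosuppressant / oncology	
Ripasudil	Dkk1	inhibit	unknown	ok	TRUE	glaucoma	waiver: possible role in blood-brain-barrier integrity
Astaxanthin	ROS	inhibit	permeable	ok	FALSE	antioxidant supplement	target_node is a synthetic placeholder (exact model target unpublished in main text)
Ibrutinib	MAPK	inhibit	permeable	ok	FALSE	chronic lymphocytic leukemia	target_node is a synthetic placeholder (exact model target unpublished in main text)
Imipramine	GSK3b	inhibit	permeable	ok	FALSE	depression	target_node is a synthetic placeholder (exact model target unpublished in main text)
Abemaciclib-methanesulfonate	mTORC1	inhibit	permeable	ok	FALSE	breast cancer (CDK4/6 inhibitor)	target_node is a synthetic placeholder (exact model target unpublished in main text)
Danthron	BACE1	inhibit	permeable	possible_carcinogen	FALSE	laxative	target_node is a synthetic placeholder (exact model target unpublished in main text)
Venetoclax	apoptosis	inhibit	permeable	ok	FALSE	chronic lymphocytic leukemia	target_node is a synthetic placeholder (exact model target unpublished in main text)
Nicotinamide	GSK3b	inhibit	permeable	ok	FALSE	vitamin B3 supplement	target_node is a synthetic placeholder (exact model target unpublished in main text)
Fenofibric-acid	Dkk1	inhibit	poor	ok	FALSE	hyperlipidemia	target_node is a synthetic placeholder (exact model target unpublished in main text)
Rosiglitazone	GSK3b	inhibit	poor	ok	FALSE	type 2 diabetes	target_node is a synthetic placeholder (exact model target unpublished in main text)
Clinofibrate	Dkk1	inhibit	unknown	ok	FALSE	hyperlipidemia	target_node is a synthetic placeholder (exact model target unpublished in main text)
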