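drugs	condition
Astaxanthin	APOE4
Ibrutinib+Imipramine	APOE4
Flibanserin+Everolimus	APOE4
Ripasudil+Flibanserin	APOE4
Ripasudil	LPL
Ripasudil+Abemaciclib-methanesulfonate	LPL
Danthron+Venetoclax	unspecified
Danthron+Nicotinamide	unspecified
Fenofibric-acid	unspecified
Rosiglitazone	unspecified
Clinofibrate	unspecified
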