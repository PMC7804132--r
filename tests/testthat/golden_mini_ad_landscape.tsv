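attractor_id	cycle_length	basin_count	basin_ratio	ROS	MAPK	CREB	APP	Dkk1	WNT_can	WNT_noncan	BACE1	Abeta	NMDAR	PTEN	PI3K_AKT	GSK3b	mTORC1	autophagy	ptau	apoptosis	synapse_loss
000001000101010000	1	65536	0.25	0	0	0	0	0	1	0	0	0	1	0	1	0	1	0	0	0	0
000001000110001000	1	65536	0.25	0	0	0	0	0	1	0	0	0	1	1	0	0	0	1	0	0	0
111110111000101010	1	65536	0.25	1	1	1	1	1	0	1	1	1	0	0	0	1	0	1	0	1	0
111110111010101010	1	65536	0.25	1	1	1	1	1	0	1	1	1	0	1	0	1	0	1	0	1	0
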