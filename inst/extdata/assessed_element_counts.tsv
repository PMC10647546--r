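element	n_total	pos_total	n_none	pos_none	n_any	pos_any
any_positive_screen	250	243	181	175	69	68
enteral_nutrition	250	202	181	146	69	56
food_allergies_2plus	250	6	181	4	69	2
intubation	250	84	181	64	69	20
parenteral_nutrition	250	56	181	29	69	27
rd_identified_risk	250	42	181	28	69	14
pnst_positive	250	37	181	13	69	24
anthropometric_flag	250	72	181	32	69	40
intake_lt50_3d	250	10	181	7	69	3
npo_gt3d	250	3	181	3	69	0
weight_loss_ge5pct	250	3	181	3	69	0
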