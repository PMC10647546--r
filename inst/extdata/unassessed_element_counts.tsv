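element	n	pos
any_positive_screen	918	385
enteral_nutrition	918	295
food_allergies_2plus	918	14
intubation	918	102
parenteral_nutrition	918	0
rd_identified_risk	918	0
pnst_positive	918	27
anthropometric_flag	918	121
intake_lt50_3d	918	6
npo_gt3d	918	2
weight_loss_ge5pct	918	2
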