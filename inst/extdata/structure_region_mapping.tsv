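structure	region_name
FL	Frontal_Inf_Oper_L
FL	Frontal_Mid_L
FL	Frontal_Mid_R
FL	Precentral_L
Ins	Insula_L
CgG	Cingulum_Mid_R
HP	Hippocampus_L
HP	Hippocampus_R
PHG	ParaHippocampal_L
PHG	ParaHippocampal_R
PL	Parietal_Inf_R
PL	Parietal_Sup_R
PL	Precuneus_L
PL	Precuneus_R
PL	Paracentral_Lobule_L
Amy	Amygdala_L
GP	Pallidum_L
GP	Pallidum_R
Str	Caudate_L
Str	Putamen_L
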