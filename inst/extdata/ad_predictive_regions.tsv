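region_name
Amygdala_L
Caudate_L
Hippocampus_L
Hippocampus_R
Frontal_Inf_Oper_L
Parietal_Inf_R
Insula_L
Putamen_L
Cingulum_Mid_R
Frontal_Mid_L
Frontal_Mid_R
Pallidum_L
Pallidum_R
Paracentral_Lobule_L
ParaHippocampal_L
ParaHippocampal_R
Precentral_L
Precuneus_L
Precuneus_R
Parietal_Sup_R
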