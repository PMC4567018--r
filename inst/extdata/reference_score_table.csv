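factor,level,five_year_rate,score
qol_level,nondeficit,63,6
qol_level,deficit,30,3
age_level,lt60,67,7
age_level,60to70,65,7
age_level,70to80,48,5
age_level,ge80,38,4
sex_level,female,65,7
sex_level,male,51,5
ecog_level,ps01,62,6
ecog_level,ps234,24,2
smoking_level,quit,59,6
smoking_level,kept_smoking,28,3
size_level,le2cm,69,7
size_level,gt2cm,50,5
nodal_level,none,65,7
nodal_level,ipsi_hilar,46,5
nodal_level,ipsi_mediastinal,33,3
nodal_level,contralateral_mediastinal,13,1
mets_level,absent,61,6
mets_level,present,11,1
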