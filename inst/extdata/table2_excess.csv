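compound,fragment,fragment_mass,tracer,M1_percent,M2_percent,sd_M1_pp,sd_M2_pp,censored
alanine,alanine,260,naphthalene_U13C,2.4,0.4,0.4,0.2,FALSE
aspartate,aspartate,418,naphthalene_U13C,3.8,0.5,0.3,0.2,FALSE
glutamate,glutamate,432,naphthalene_U13C,6.4,2.0,0.3,0.4,FALSE
fatty_acid_C16_1,mclafferty,74,naphthalene_U13C,2.8,1.5,NA,NA,FALSE
fatty_acid_C18_1,mclafferty,74,naphthalene_U13C,1.0,0.5,NA,NA,TRUE
alanine,alanine,260,bicarbonate_13C,7.8,0.1,0.3,0.0,TRUE
aspartate,aspartate,418,bicarbonate_13C,11.3,0.5,0.3,0.0,FALSE
glutamate,glutamate,432,bicarbonate_13C,10.5,0.4,0.3,0.0,FALSE
fatty_acid_C16_1,mclafferty,74,bicarbonate_13C,11.0,2.2,NA,NA,FALSE
fatty_acid_C18_1,mclafferty,74,bicarbonate_13C,5.7,4.4,NA,NA,FALSE
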