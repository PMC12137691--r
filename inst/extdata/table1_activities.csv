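assay,enzyme,direction,activity,uncertainty,coupled
citrate_synthase_ox,citrate synthase,oxidative,2.0,0.7,FALSE
citrate_synthase_rev,citrate synthase,reductive,0.05,0.008,FALSE
aconitase_idh_ox,aconitase + isocitrate dehydrogenase,oxidative,3.6,0.42,TRUE
isocitrate_dh_ox,isocitrate dehydrogenase,oxidative,65,9.5,FALSE
ogor_ox,2-oxoglutarate:ferredoxin oxidoreductase,oxidative,1.1,0.20,FALSE
succinate_dh_ox,succinate dehydrogenase,oxidative,70,15,FALSE
succinate_dh_red,succinate dehydrogenase,reductive,9.4,0.58,FALSE
fumarase_ox,fumarase,oxidative,0.15,0.01,FALSE
fumarase_red,fumarase,reductive,1.1,0.46,FALSE
malate_dh_ox,malate dehydrogenase,oxidative,0.88,0.24,FALSE
malate_dh_red,malate dehydrogenase,reductive,2.9,0.51,FALSE
co_dehydrogenase,carbon monoxide dehydrogenase,oxidative,94,14,FALSE
formate_dehydrogenase,formate dehydrogenase,oxidative,440,83,FALSE
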