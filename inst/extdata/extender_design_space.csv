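name,unit,lower,upper,reference,active
tris,percent_vv,0,50,50,TRUE
egg_yolk,percent_vv,0,20,20,TRUE
milk,percent_vv,0,15,15,TRUE
fructose,percent_wv,0,1.25,1.25,TRUE
glycerol,percent_vv,0,7,7,TRUE
ethylene_glycol,percent_vv,0,6.75,6.75,TRUE
trehalose,mM,0,100,100,TRUE
clc,mg_per_ml,0.5,1,1,TRUE
glutathione,mM,0.5,0.5,0.5,FALSE
melatonin,mM,2,3,3,TRUE
ngf,mg_per_ml,0,0.5,0.5,TRUE
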