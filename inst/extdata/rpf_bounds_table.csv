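compound,abbreviation,lb,ub,is_reference,has_emission_data
"1,3-Butadiene",but,30.3,56,TRUE,TRUE
Acrylonitrile,can,5.76,192,FALSE,TRUE
Allyl glycidyl ether,age,0.089,2.69,FALSE,FALSE
Acetaldehyde,ald,0.469,0.931,FALSE,TRUE
Alpha-methyl styrene,ams,0.583,5.39,FALSE,FALSE
Benzo[a]pyrene,bap,29.3,187,FALSE,TRUE
"1,2-Dibromo-3-chloropropane",dbcp,8.95,26.6,FALSE,FALSE
"1,2-Dibromoethane",dbe,0.575,1.67,FALSE,FALSE
Decalin,dcn,0.0175,0.11,FALSE,FALSE
Ethylene oxide,eox,21.7,71.5,FALSE,TRUE
Formaldehyde,fal,68.2,129,FALSE,TRUE
Hydrazine,hyr,5.65,560,FALSE,FALSE
Isobutyl nitrite,isn,0.176,3.7,FALSE,FALSE
Naphthalene,nap,0.339,0.726,FALSE,FALSE
Nitrobenzene,nbz,0.115,11.3,FALSE,TRUE
Propylene glycol mono-t-butyl ether,pge,0.61,5.9,FALSE,FALSE
Propylene oxide,prp,1.85,22.8,FALSE,TRUE
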