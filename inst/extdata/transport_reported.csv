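metric,species,source,targets,compartment,flow,load_conc,time_min,value,sd,units
percent_transferred,dextran4,POC,CC;LOC;LOOP,,TRUE,1,180,58.4,7.6,%
percent_transferred,dextran4,POC,CC;LOC;LOOP,,FALSE,1,180,20.4,3.1,%
fold_enhancement,dextran4,POC,,LOC,,1,180,2.1,0.1,fold
fold_enhancement,glucose,CC;LOOP,,POC,,13,180,1.9,0.1,fold
percent_transferred,dextran70,LOC,POC;CC;LOOP,,TRUE,1,1440,70.6,12.4,%
percent_transferred,dextran70,LOC,POC;CC;LOOP,,FALSE,1,1440,15.9,8.1,%
fold_enhancement,dextran70,LOC,,POC,,1,1440,9.1,0.3,fold
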