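condition,variable,time_h,value,sd
control,glucose,2,7.8,0.5
control,insulin,1,21.1,0.8
control,insulin,12,22.2,0.3
control,insulin,24,22.6,0.1
pa,insulin,1,22.3,0.9
pa,insulin,12,26.6,0.4
pa,insulin,24,27.1,0.5
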