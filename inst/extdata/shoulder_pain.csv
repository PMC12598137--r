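group,1,2,3,4,5
suction,16,5,0,1,0
control,4,1,5,7,2
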