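"basket","y","n","pi0"
"ATC",2,7,0.15
"ECD/LCH",6,14,0.15
"CCA",1,8,0.15
"CRC-V",1,26,0.15
"CRC-VC",0,10,0.15
"NSCLC",8,19,0.15
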