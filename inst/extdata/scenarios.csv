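"name","pi_true1","pi_true2","pi_true3","pi_true4","pi01","pi02","pi03","pi04"
"global null",0.20,0.20,0.20,0.20,0.20,0.20,0.20,0.20
"global alternative",0.35,0.35,0.35,0.35,0.20,0.20,0.20,0.20
"mixed 3",0.20,0.35,0.35,0.35,0.20,0.20,0.20,0.20
"mixed 4",0.20,0.20,0.35,0.35,0.20,0.20,0.20,0.20
"mixed 5",0.10,0.20,0.30,0.40,0.20,0.20,0.20,0.20
"mixed 6",0.20,0.20,0.20,0.35,0.20,0.20,0.20,0.20
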