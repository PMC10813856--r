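"basket","y","n","pi0"
"Angiosarcoma",2,15,0.3
"Ewing",0,13,0.3
"Fibrosarcoma",1,12,0.3
"Leiomyosarcoma",6,28,0.3
"Liposarcoma",7,29,0.3
"MFH",3,29,0.3
"Osteosarcoma",5,26,0.3
"MPNST",1,5,0.3
"Rhabdomyosarcoma",0,2,0.3
"Synovial",3,20,0.3
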