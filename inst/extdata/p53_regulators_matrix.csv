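,S,P1,P2,P3,P4,HDAC1,P6,P7,P8,P9,T
S,0,0.1111,0.1111,0.1111,0.1111,0.1111,0.1111,0.1111,0.1111,0.1111,0
P1,0.1429,0,0.1429,0,0.1429,0.1429,0,0,0.1429,0.1429,0.1429
P2,0.2000,0.2000,0,0,0,0.2000,0,0,0.2000,0,0.2000
P3,0.2500,0,0,0,0.2500,0.2500,0,0,0,0,0.2500
P4,0.1250,0.1250,0,0.1250,0,0.1250,0,0.1250,0.1250,0.1250,0.1250
HDAC1,0.1111,0.1111,0.1111,0.1111,0.1111,0,0.1111,0,0.1111,0.1111,0.1111
P6,0.2000,0,0,0,0,0.2000,0,0,0.2000,0.2000,0.2000
P7,0.5000,0,0,0,0,0,0,0,0,0,0.5000
P8,0.1429,0.1429,0,0,0.1429,0.1429,0.1429,0,0,0.1429,0.1429
P9,0.3333,0,0,0,0.3333,0,0,0,0,0,0.3333
T,1.0000,0,0,0,0,0,0,0,0,0,0
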