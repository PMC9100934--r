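peak,gp
P1,GP1
P2,GP1
P3,GP2
P4,GP3
P5,GP4
P6,GP5
P7,GP6
P8,GP7
P9,GP8
P10,GP9
P11,GP10
P12,GP11
P13,GP12
P14,GP13
P15,GP14
P16,GP15
P17,GP16
P18,GP17
P19,GP18
P20,GP19
P21,GP20
P22,GP21
P23,GP22
P24,GP23
P25,GP23
P26,GP24
P27,GP25
P28,GP26
P29,GP27
P30,GP28
P31,GP29
P32,GP30
P33,GP31
P34,GP32
P35,GP33
P36,GP34
P37,GP35
P38,GP36
P39,GP36
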