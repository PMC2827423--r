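line,position,normfinder,bestkeeper,qbase_m,qbase_cv,genorm_m
Mitchell,1,EF1a,CYP,EF1a,EF1a,RAN1
Mitchell,2,CYP,EF1a,SAND,SAND,SAND
Mitchell,3,RPS13,RPS13,RAN1,RPS13,UBQ
Mitchell,4,UBQ,ACT,RPS13,RAN1,EF1a
Mitchell,5,ACT,UBQ,CYP,CYP,RPS13
Mitchell,6,SAND,TUB,UBQ,UBQ,CYP
Mitchell,7,TUB,SAND,TUB,TUB,TUB
Mitchell,8,GAPDH,RAN1,ACT,ACT,ACT
Mitchell,9,RAN1,GAPDH,GAPDH,GAPDH,GAPDH
V30,1,UBQ,CYP,ACT,RAN1,RPS13
V30,2,RAN1,EF1a,RAN1,CYP,UBQ
V30,3,ACT,ACT,CYP,ACT,RAN1
V30,4,GAPDH,SAND,TUB,TUB,CYP
V30,5,RPS13,UBQ,RPS13,RPS13,ACT
V30,6,SAND,GAPDH,UBQ,UBQ,TUB
V30,7,EF1a,RPS13,EF1a,EF1a,EF1a
V30,8,TUB,RAN1,SAND,GAPDH,SAND
V30,9,CYP,TUB,GAPDH,SAND,GAPDH
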