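cluster,trait,n_above
A,tpc,12
B,tpc,27
C,tpc,12
D,tpc,12
E,tpc,14
F,tpc,23
G,tpc,13
A,anthocyanin,8
B,anthocyanin,20
C,anthocyanin,3
D,anthocyanin,2
E,anthocyanin,1
F,anthocyanin,22
G,anthocyanin,2
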