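min_aa,max_aa,n110,n20
51,100,10,2
101,150,10,2
151,200,10,2
201,250,10,2
251,300,10,2
301,350,10,2
351,400,10,2
401,450,10,2
451,500,10,1
501,550,10,1
551,600,10,2
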