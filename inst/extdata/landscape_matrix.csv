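fragment_id,a,b,c,d,e,f,g,h
f1,1,1,0,0,0,0,0,0
f2,1,1,1,0,0,0,0,0
f3,1,1,1,1,0,1,0,0
f4,1,1,1,1,1,0,1,0
f5,1,0,0,1,1,1,1,1
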