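"r01","r02","r03","r04","r05","r06","r07","r08","r09","r10"
0,1,1,0,1,0,1,0,0,0
1,0,1,0,0,1,0,1,0,0
1,1,0,1,0,0,1,0,0,0
0,0,1,0,0,0,0,0,0,0
1,0,0,0,0,0,1,0,0,0
0,1,0,0,0,0,0,0,0,0
1,0,1,0,1,0,0,0,0,0
0,1,0,0,0,0,0,0,1,0
0,0,0,0,0,0,0,1,0,1
0,0,0,0,0,0,0,0,1,0
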