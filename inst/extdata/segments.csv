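id,length_m,embedded,reach,gravity,cross_body
1,0.350,TRUE,TRUE,ground,large
2,0.320,TRUE,FALSE,ground,small
3,0.320,FALSE,TRUE,ground,small
4,0.350,FALSE,FALSE,ground,large
5,0.415,TRUE,TRUE,against,large
6,0.400,TRUE,FALSE,towards,small
7,0.400,TRUE,TRUE,against,small
8,0.415,TRUE,FALSE,towards,large
9,0.276,FALSE,TRUE,against,large
10,0.415,FALSE,TRUE,towards,large
11,0.400,FALSE,FALSE,against,small
12,0.400,TRUE,TRUE,towards,small
13,0.415,FALSE,FALSE,against,large
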