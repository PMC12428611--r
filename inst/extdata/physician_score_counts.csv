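rater_id,n0,n1,n2,n3
P1,4,12,27,9
P2,1,10,23,18
P3,2,10,27,13
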