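kind,name,value
pairwise,k12,0.537
pairwise,k23,0.459
pairwise,k13,0.643
model,k1,0.649
model,k2,0.645
model,k3,0.528
consensus,kcons,0.586
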