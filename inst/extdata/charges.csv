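residue,site,charge,vsite_dist
SOL,OW,-0.8476,
SOL,HW1,0.4238,
SOL,HW2,0.4238,
SOL,DW,0.4238,
SOL4,OW,0.0,
SOL4,HW1,0.5897,
SOL4,HW2,0.5897,
SOL4,DW,0.5897,
SOL4,MW,-1.1794,0.1577
DMS,S,0.139,
DMS,O,-0.459,
DMS,C1,0.16,
DMS,C2,0.16,
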