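histology,overall_n,overall_pct,t1gad_n,t1gad_pct,pet_n,pet_pct,petminus_n,petminus_pct,flair_n,flair_pct
astrogliosis,54,19,4,4,9,8,3,27,38,53
G2,45,16,5,6,21,19,6,55,13,18
G3,125,44,55,60,51,46,2,18,17,24
G4,60,21,27,30,29,27,0,0,4,5
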