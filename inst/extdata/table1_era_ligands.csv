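ligand,cid,ic50_nM,score_kcal_mol,predicted_ic50_nM
Hydroxytamoxifen,449459,40,-9,278.38
Caffeic Acid,689043,120000,-6.4,21800
Bazedoxifene,154257,26,-8.5,643.90
Lasofoxifene,216416,1.08,-8.4,761.48
Fulvestrant,104741,4.4,-8.3,900.52
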