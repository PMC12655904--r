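ligand,cid,ic50_nM,score_kcal_mol,predicted_ic50_nM
Estradiol,5757,46,-10,52.0
Raloxifene,5035,7.7,-11.1,8.79
QYA,145949437,5000,-6.97,127000
Benzoxazole,9228,5.4,-11.3,6.18
Hydroxytamoxifen,449459,23000,-6.23,36700
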