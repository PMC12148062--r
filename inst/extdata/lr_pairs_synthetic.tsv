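lr_pair	ligand_gene_symbol	receptor_gene_symbol
Pdyn_Oprk1	Pdyn	Oprk1
Pomc_Oprd1	Pomc	Oprd1
Bsg_Cav1	Bsg	Cav1
Vegfa_Kdr	Vegfa	Kdr
Dll4_Notch1	Dll4	Notch1
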