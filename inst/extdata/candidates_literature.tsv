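name	parent_id	formula	smiles
Atenolol-LS1	atenolol	C14H21NO4	CC(C)NCC(O)COc1ccc(CC(O)=O)cc1
Sulfamethoxazole-LS1	sulfamethoxazole	C12H13N3O4S	CC(=O)Nc1ccc(cc1)S(=O)(=O)Nc1cc(C)on1
Sulfamethoxazole-LS6	sulfamethoxazole	C16H14N8O4S	
Ketoprofen-LS24	ketoprofen	C16H14O4	
Ketoprofen-LS25	ketoprofen	C22H24O9	
Ciprofloxacin	enrofloxacin	C17H18FN3O3	
Tetracycline-LS2	tetracycline	C21H22N2O7	
Tetracycline-LS3	tetracycline	C22H22N2O7	
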