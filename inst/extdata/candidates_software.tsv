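name	parent_id	formula	smiles
Enrofloxacin-M242	enrofloxacin	C19H22FN3O4	
Erythromycin-M46	erythromycin	C29H53NO9	
Erythromycin-M361	erythromycin	C37H67NO14	
Ketoprofen-M648	ketoprofen	C16H16O3	
Ketoprofen-M835	ketoprofen		OC(=O)C(C)c1cccc(C(O)c2ccccc2)c1
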