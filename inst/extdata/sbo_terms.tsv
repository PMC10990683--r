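SBO:0000012	mass action rate law
SBO:0000028	enzymatic rate law for irreversible Michaelis-Menten kinetics
SBO:0000240	material entity
SBO:0000243	gene
SBO:0000245	macromolecule
SBO:0000247	simple chemical
SBO:0000252	polypeptide chain
SBO:0000253	non-covalent complex
SBO:0000290	physical compartment
SBO:0000297	protein complex
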