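# Minimal defined medium for L. reuteri ZJ625 (g/L).
component	group	concentration
Glucose	carbon	15
Tween 80	surfactant	1
K2HPO4	buffer_salt	3
KH2PO4	buffer_salt	3
MgSO4.7H2O	mineral	2.5
MnSO4.4H2O	mineral	0.025
NH4Cl2	buffer_salt	1
Sodium acetate	buffer_salt	5
FeSO4.7H2O	mineral	0.02
L-Alanine	amino_acid	0.1
L-Isoleucine	amino_acid	0.2
DL-Methionine	amino_acid	0.1
L-Arginine	amino_acid	0.1
L-Phenylalanine	amino_acid	0.1
L-Histidine	amino_acid	0.25
Glycine	amino_acid	0.1
L-Threonine	amino_acid	0.1
L-Leucine	amino_acid	0.1
L-Glutamine	amino_acid	0.2
L-Glutamic acid	amino_acid	0.2
L-Asparagine	amino_acid	0.2
L-Tyrosine	amino_acid	0.1
L-Serine	amino_acid	0.1
L-Tryptophan	amino_acid	0.1
L-Cysteine	amino_acid	0.2
Guanine	nucleotide	0.01
Thymidine	nucleotide	0.01
Uracil	nucleotide	0.01
Cyanocobalamin	vitamin	0.001
Pyridoxal	vitamin	0.002
Pantothenic acid	vitamin	0.001
Riboflavin	vitamin	0.001
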