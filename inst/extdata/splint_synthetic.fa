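>splint_synthetic_386bp fixed pseudo-random splint fixture
CCCTCGCTGAGTAGCCCGGTGCCCTCGGGGCAGAGCGTGAAGCGAGCTTCAGTCAAGTTG
GAAGACGCCAACGACATAGCGATTCAGTCAATTGCTTCAACAAGCGCAAATCGCTCCACG
AGCAGGTAATCAGGGTGATAGGGAACTGCCATGTAAATGACTACATCCGCCGTCAAAATG
AGGTGTATATATAACACGGACGTGGTGGAATCCAAACTTACCAGCATCTTACTAAATTGA
ACGACCTGAGTAATGCGGGTGGCTTAACATTATGGTCCGGGAGCTACAGTAATTAATTTA
TCGAAAACGTTTCCTGCGATGGCTGTGCCGGCACATGAGCGGCTGGCCGACGCCCTGCGC
AGAATTATAAGACACCCCCAAGCTAT
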