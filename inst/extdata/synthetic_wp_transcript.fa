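>synthetic_wp_scaffold synthetic demonstration sequence
AGCAGTTGAATTTGGAGAACCTATGGGAACCGTTATTGAATTTCTAATTTGTCCAGAACA
ATGCTGCTGCACAGTGCAGTCTCTTGCCATGACAGCGTAAAGACAATTGGTGTAGCCCGC
GCTATGGCTGATTTGACTGTTAACCCGAGGGGCAAAATTAATCAAGGCCGACGGCAGGGA
TAGAAATAAAGAGTCTAAGTACGTCTTCCCTTTCTTATATCGCTATGTACGCGCTCGGCG
AAGGATCAAGCGGCTACCACAATCATGTGACTTTGCAATGTGTCTGCCATGTTTTCACTG
AATGTAAGATGAGAGCCAAGCGGAGGACCTCGAGGCGGATCGGACGGTAAGAGAGATGCC
TGGAGATCACATCCCCTAGTACGTGCAGAT
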