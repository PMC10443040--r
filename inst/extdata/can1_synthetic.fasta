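>CAN1_synthetic synthetic stand-in sequence, seeded random 1773 bp
TAGAATAGGCTTTATTACAGTCTGATGAAAAAGGAGATTTTCGCCGACCCGTGTCGACTA
CTCAATAAAGGCCTGTATAATACATACCGGTATCCAATGCACAAAGTTGTTACTAATTTC
GCCTCCTGGTAGATGGTCTGAGAAACGTAATACCCGTGTTCGAGGGAGGTCCTTCAAAAA
ACACTTGAGAGTCGAAGAGCTTCCCTTACTAGTCTACGAATTTAAATTATTTTCCCAAAC
AGATAATCGTACAAGGAAATGAGCCTGGGAGTGCAGTACTCTTCCTGAGAGGCATCCCGA
ATAGTCTGCGTTATCCTAAAAAGGAAAGGCAGGAGACCTCACGACGAAACAAGTCCTCAG
GAGCCGTCCCGAAGCCGTCGTATGGTTTGTTTGGGCGGGAAAAAACAGAGTCGTCACCTA
TTTTACACGAGGAAACCTACAGGGTAGGACCTTCTGGTAATACCCTAGGATCGGACGAGG
CTGCCCCCCAGCGTCATAGCGGCGGAGATAAGAGAGTATGAAAAGGAATAGAACTCGTAG
CGGTTCGCTATTACAGGCCATGGAGAGTCATTTCACGCTAAACACAAAGAAACAACCAGT
CAGGCTACGAGGTGGGCGATCTGCAAGTATTATTTCGTTGCCCGTGCTACCTGGGCTGAA
TGTCACAGGCTCGGATGATGGAGACTGTACAGCTGTGCCGTGCATGTGGTATCTATAGAA
TTTCGCGACTAACAAACGGCGAGAGGGGATGTTAAACATTAGGATACTTTATCTTTTCTC
AGGATTAGAGTGCCATAATGTCGGGAGCACCGCTGCGCTCACTATTTTTACAGCCCCACT
AAGTAATCCTCCTGCTTTGAAGGTCCCACGGTAAATGCACAGTTAAGATAGTGGCGGCCT
CAATATGCTTTCGGCTGGAGAACACGTCCCCCAGGGTATTCTCGCTGATCAGACTTACGG
ACTGAGAGCCAGCTAAATTCAATGGGGAGGACGTGTCTCTGACATTGCATTTGTTGGGGG
CTGGCAGGAGACAAATAACCGAACTCGGGTTAAGCACCTTCCTTCGGGAACACATGCTTG
CGGTATACTCCCCAGGGAACGGTCAACGACCACAGTAGTCGACCGTGACTCCGTATATTA
CCACCGTATACTAGTAACGTTGCGAGAGATGTCGGAGTTGATCTGCGGGTATCCCCGGTA
GATCAGGGGCACATATCTCCAGATCAAGTCAAGTTCTTTCGTTTGTCACCAGGAATAACT
AATTTCGATGCTCATCGCGAGTGTCTAAGGTTACCATCGAGCATTCTATTAGGTGCCCCT
TGTACTGGTCACCCGGTGTGCCTTATAAGCTGGAACTTCATACCCGCGTGCCATACACCA
ACGACGCCAGTGGTCACTATTGATATTGGTTTGTTATCTATAGGGAATAATTACCCGACG
TAGTACGAATGACAATCTATGTAGGGCAATGTAGCTGACACATTACTCTCACGTGTGCCT
CGTAAAACGAGGAGGTTTGGGACTGGTACTGTCTTACCATCACTCCTCAACCAACACTTC
TTGTTAAGTAAGACTGGCGAATATAGATTCGCGCCGTACCTGAAAAACTAGTTGGACGAT
GGACTATCGCGTGTGTTATGGTAACCACGATTATAGAACCATGACCTTTGTACACCCTGT
AGTCCACTTCGTGGCAATCGGTGAAAGGAGCGGGCGCATATTGAAAACCCCGTGCATACG
GAAATGCTCTCGTCGTCTCAGGCGAATTAAAGA
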