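>synthetic_vertebrate_coi
ATGACAGGCCGGAAACCCCGAGAAAACAACCCATGATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACC
CCAGGTCGGTCTGGATATATAGCTGAATCATTTAAAGCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTA
TGGTATCTAGCGGAACCCTTAAACAGCGGCGGTAATCTCACGGGGGTATGATGTCTATGATCACCCGACG
GGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCCATAACCCT
CCACTCCTCTAATTGTTACTAAGAGACCCTGAGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATTA
ACATATGCGAGCATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAG
CCTGAAGCAGGAGCATCCTTCTTACATAACTATTCTCAACCAACCACAAAGACTGAGAAGTAGGGTCAAC
GTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGGCCACGCTCCAAAACAACTCAATTAGTCCTACTTGTG
ACATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCCAGGGTCCCATGTGAGGATCA
CGTGTCCCACATACCCTGTTAGCGTTTTGTGTCCAGCGACCCGTATGAATAACATGAGCTTTTACGGTTT
TTCTAAGACAAGGCTTGCTAGAATAAACAACATAAGCTTCTGACGGCAACGCTCTGCGGAGCTCGGCAAT
TCACAAAGCACAGACAAGCTTAAGAACACTGATTAGTTAGAGAAAACTTTACTTCGTCGTCCCGCCATTG
TTCGATAGTGCAACTACCCTCGCAGAGACGTGCATTTAATTCATGCCGGGGAATTACCTGTTATTCCCTG
ATTTACATCGATCACAAGTAGCAGCCTCGCGTACGCAACACTACCGCAGTCCTGAATCCTTTCAACCTAT
GTACGAGGTAAAAGAGCGGGTTGGAGTTACATCCCCCGCGTCGACGCGATGCAACAACACTCCTAATCAA
CAGTTGTGACTCTTAGGCACAATGACTCCCTTCCCAGGAAACTTGATTTTTTGGTCATCCTGAATTGCCT
TAGGATTAGCATGACTGACGCGAATGCGCCTGGTGGCCCTGTTTTGATACCGCAGTCTTTAGCTGACGGA
CTTGCGTGTAATGTACGGCTCCGGTATTCGGCGCAAAGTACCTTGGCCTATATAAGGTCTAAGCAATGTT
ATGTCCAGACCAGCGAAACTTCTCAGTAAGAGCTCGTGGATTGATTCCCATATTGGTGCGCCGCTCTTCA
AGTTTTGTACCATTCAGATAAGGTTGCAGAAGGCTCAACTTGTTCCCCTGTTCAGATAGTAGGTGCACTC
GTCAGGCCAAGTCTGTCGAGAGTACCGAAATCATTCGCGCCGTCGAATGACGGGTTTTTGAATAGCATAA
AACTATCCAATTTCACCGAAATTCCAGCGGAGCGGCCTACTTGGAAGATTCGCACATTTTGCGAGTGACG
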