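seq	expected
AAGCCCAATAAACCACTCTGACTGGCCGAATAGGGATATAGGCAACGACATGTGCGGCGACCCTTGCGACAGTGACGCTTTCGCCGTTGCCTAAACCTATTTGAAGGAGTCTAGCAGCCGCAGTAAGGCACAATACCTCGTCCGTGTTACCAGACCAAACAAGACGTCCTCTTCAATGTTTAAATGACCCTCTCGTCATAAAACCTTTCTACTATGTGTTCCGCAAGAATCAACAACTACAATGGCGCGTCGTGAATAACGCGACGGCTGAGACGAACGGCGCGTGAATGAAGCGCTTAA	0.8918
ACAGCTCAGGAGCCAGTCCCCTACGTCGCATATCCTGGCCACTGGAGGTGAAGCGAATGGTATCGATACGTAGGAGGTGTGCCTTCGTAGGCTGTTTCTCAGGACGCCCAACTATTCTTTCCAATCCTACATCTGTTTCTTGCGTCGTAGCGGGACCCTCCATTGTTACTTATTAGGTTCTCGTTATGTCTCATAATCTCAGTGCTGGTGTGATAAGCAAACCACCCTACTGGCACGAAGTTCACAGAAGTGAGATTATGTCTCGTTTGGCAGTCTTGATGCTCGGGGGACACTTCTTTA	0.8808
AGCTCGGTGTGGTGGGCACGACCCTGGACGCGCGACGAAGCTAAGTTTGCAGTAATTAACCGACATCTTTGTGAACCGACCCACATTTGACGGTACGCTACCGCAACGGTATGTGTTAATGGAACAGACTTGCTTATGTGGACGTTGTATAGGGATATTACGTTACGCGTTAACCGATACATACTGGTTTCTCTCCAGTGGAGGTCTTGGTTGCCTCTAGTTTCTACGATATACTCATGGTAGTGTAACGCATAATCGAAGAGGGTCCTCCCATCTCCTGTGATGCATGGTGTGCTTACT	0.7673
GGGATGAATGCGCCGCAAGTAGCAGGTCCCGGCGTGGATACCTGATAGATGGTGACTAGCATGTACAAGTAACCTTGTCTATTGAGCTTCGAGGATGCATACAAGCCCACCCGCAGCCGCAACAGCGACGACTAATTGATCAGTAATTTATTAAGCACGGTGTTAACTTCTGTTTAGTGGGCTAAAATAGCAGATGTAGGGACCTCAGGAGCTAGACGGGGACCTACAACTTTGCGGGAACCAAGTTTTTGCAGTAGTGACTAACGCCGGGAATTCCTCGATATATAGTTTGATAGCTGA	0.6918
TACTTATGGCGCAACGGCCACGCCCACTTTGGCTATTGGAGAGTTAAGGAATTATCGTCATAGACACTTCGGGTTGAGAGATGGCGACGGTCAGTGCATGAGGCCGTCCCCAGAAGCTCCCCTATGCTGTCCGTCGTTGTTCCCGATGAAGACGTCTACTGATATGCTAGCAGAGCCAGTCTTAAAGCCTAGCGAACTTAATACCGTAGCTCAGAATTATGGAGAGCAGCAGGCTTCCATAGCACAGGTTGACGGAGGAGTTTTGCTTGGATATCGGAAGGGTTCTGTAGTGAATGCACT	0.8754
ACACGGTACTGGTACGTGGCAACTTAGGTCGTCACATCTAGGAGGCCGCACCCTAGGTCAAGTTTTACGATTGCCCTAACGCCGCGGAGCGCGACCCGAAAAGCTATGGTCTGTAACTTTTCGCGGGTCGAGCTAGTCCAAGTTCCGGCCTTTGTAATTCCGAAGTTGAATCGGTGATACGGATTGACATGGGCCTAAACGTTCCGGCTGGTGTAGGATGATGCATCTCCAACATGTCTCTTACCGTTGCTGGGTCCGGCGGCTGTGGGATTGCGAGAGTGTCCGGCACCACCAATGTAC	0.8966
ACTTTCGGGAACACTCATTCGAAGAGGTTCTGCAGCTGCAGGCCTTGATACCTGCAGTCTGGGAGGCAATGCTGAGGCCCTCTGTTCCATGAAACCCGTACTATATCTTATGATGACAATGAAATAGTCCTGTTTTACGACTCCAAGTTTCCTGCGCAATACCAAATACATTCCACGCGGCGCCTGGACTTAGTGTTCGTCTCCGCTATTCTCGCGATGACAGTAACCTCGGACCATCCTCGGTTGGGGTTATGCGGTACCAGTGCCGCTCTGGTTTCGCCTCAAAAATCCACACTGATT	0.7897
AATAAGGATCAACCCGGGTAGTTCCGAAATTTTAACATTGAACCTGAAGACGACCTAGCCTGTCAGAATCAGTGAGTTCGTTCTAGCAAGCTCTGGAAAGTGGACACTTTAAAGAGTAGTTACCTCCGGGTCACTGTGTAGGCTCTACGATGTGTGTCGGCTGCTGGTCGTGTGACCATCTGATTCGCGCTTATTTTAGAACGCATGTAAAGCCTGTTCGATAGTAACGGGTCTGTATTGAGAAAGACCCCGTTCTCCTTACTTTACCGAACGGCTAGTGTTAGGTCGACGACGACGCTT	0.745
CTTCTCCTGCCGTAGATCCTTTTTTTCAACGAGCGCTTAAGGATCTACGATGGATACCGTCCCCAGGCGGGGACTAGCCCCGCTTCGTTTAATGGTTGAATGATCTCTGGGGCTGAAATAACTTATCCGCGAGGAGCATGCTAAACTACCTAAGATCTACTAAAGGGCTCCAACTGCCTTCAACATGTGCCGACGAGCCTGACTTACTAAGGCTTGCTAAAAGCAATGTTTACGAGACCGTAGTCACATATAGCAACACTGGCGCGAAGTGAGATTGATCGCGAACAAACATGTCCATCG	0.686
CTGGAGAACCATATGGGATAGCGGCTGTCCCATACGAGATGACCTTACGAACTGTAACTAATCCGGGTGGTGCACCACACTTGTAGCTGTGAACGACGCACGTAGGCATTCATACAAACCCTGAGAAACTCAGAATACTTTATTCGCCGGTCACGTTTAAGTCTCCATGTTGGTGCAGCAGATGCCACCGACTGCCCGGAGCCTGCTAAACCATAGCCGCGAACCAGAGTAGGGCCTTGCGCCTGGCCATACGCATCGACGGCAGTAGCCAGGAAATTTCTTTGTATCCTAAGAGGAAGC	0.6441
TCAAGTATCTCAAGCCTGGGCAATTCAGATAGTCAACCGATAGTTTGATCGTGCTAGTTGCGACAAGTCATTTCTGATACATCCCCCATATCCGGAATTGGTATATCCAAAGGTGTTTACGTCTATGCATGGAGGGGTACCGTGGTACTCTTGACAGTCACCCACATAGCGGTTAACGTTCTGGCGAGATACCCCCGTAATCCACGGGTTGTGCTGTAAGGGATAGGGGGGCCCATGCATGGTTTACGCTGGCCGATCGCGACGCGTGGGGTATAATCATGTACCCGTTCGCATGCGAAT	0.6986
GCCCTACTTTTTTAACGAGCAACCGGCATGCAAGGTGTCGTGCCTACCCCACAGATGAAAAAATTTAGTCCAGTAGCTAAGAATCCGCGTGCATCTGCAAAATCAAAGCTGGTAACAGGGTAAAACCGGTGAGGCATTTGTTTCACACATTTCTGACTTATTAAGGACGATCTGTCAACTTCATGCGGACTTCATTTATTGATAATTAAAGCTGGACTGTGTAACAGGGGAACTCTAGCCATCTCGATAATTCTAATTCCCATGTTCGTGGTCCTGGCCCGGCCGAGTTGTAAATCAACG	0.8032
CGGCAGCAGTACTCGATTTGAAGCTCGCCGTCACCATATGGCCGAGTCACGAGTGAGCCACTTAGCCGGGGCTAAGTCCAGTATGGAGTTAGCGAACAACCTACTACATGAAAACGACGTTTTTGATAAAAAGAGGAGTTTATCCCTGCGGACAAATAGCGCTCCCCGCACATAGAGACTGGCCAGACGTTGGCGGTCAGCCTGGCGTTTGGTACAGCCGAAAATCAGTCGTCGCTATGACCCTCCCTGACTCAGGCACGTTTAAGAGGCTTGAGTCTGGTTACTCCAGCCCCGACTGAT	0.7684
TTCCTACACCCACACGCTAGACTTTCCTCCGCGTACTTCAACTCACTAAATCATTGATCTTGATCGTCAGTGCAAAATCGTGACTGGTGGTCTTCGTGGGTCACTCACTGACTAACTTAAGCGAATTGACTTACGCACCAGCACAGTGTTCAAAGGGGCCTTAGCTAAGGAGGTTTCGTTATAGATCCGTGAGCGATGACTGGCGCCTCCCGCCCCGCAAATAATGGTGTCGTCCATTAGTCTATGAACTAGGGCGCGTGGCTTCTGGTGTCCCAGCTTCCCTACTTCGTGGATACACGT	0.7386
ATGGGGGGATAGCCGGGTTATGTCCGTTAACGCGGGGTGTGTTCCACCGACCTAAATAATAAGCATGCCGTCCCAAGGTTGTCCTTGGTCATGGTGCGAACGGTATTGATGCAGCTTTCCTTCGATCGGGTCACCGATTGTCGACAACAGGCTACACATCGTGTGTAGACAGTATCCGTAACTTCACTACTTGGCAAGTGCGACACTGACGATCAATCGACCTAGAAGCACTCGGTCATGCGATTGTCCGGTGCACTGGGTATCAGCGATCTCGGTGAAAACCACATCAATTGAGCAACT	0.8246
ATAGTGAGAAGACAACTCCCCTAGTTACCTGCTGGGGTTGCCTGGTTTAAGACGAGCCGAGCAATGCCGGCCGGATCAGTCTAGATAAGGTTACATAGAGCGCCATTACTGTCCGATATGATTCCTCTTCCCAGTGAATTGGCGGAGCGTCTACCGCAAACCGAGAGTTAGCCCGTCATAGCAGCGATAATGGAAGTCTAGTACCTAACGGTTCAGGGGCGAGTAGCCGTCATCTCCTGGTCCCCCGCTCCGAACGCAGTTGTGCCACCAGCCCAGATCTGCTTTCCCCATAGTCCCACT	0.9207
TGTCTTATGTAATTACTATACGTTGGTCTGACTTAACCTTGTACTCTAGGCAAATGATCTTACGCCCCATGGTGCACCAGATTTATCCTTTTAACGCACCAGACAGGAAATCCGCTGAAGGGTATAGTCAGGTCCAAATGTGGGCTTTCCGCAAATACTTAGGCACGGAGGGAAGGTACCGGTTACTCTGTTAGGACGGACGAGTCTCAGGAGTATCGTGCGCAGACATATCCGTGGCACCATTAAGAAGTAAGAGCGCCGGGTAGCCGAAACGGGCGCCAGGTACATAATAATTCTGGG	0.7915
CATCATATGTTCCCGGTCGGTTAATAGTTCGGCATAGAGTTTCCCTTAGCTTGCCATATGATCGTAATGTAACCACCTGTTCCGGGTGAATCGAGAAGAGACTTGTTTTCCTCCTGTCGCCAAACTTCACTTTCTTTTGCCTATCGTGAATGATACGTAACTAGAGATTTGTGGGCAGGATCAGAGTACAGGCGGGAACCTGCGCTCAGACCTTTCTCCGAGAACTTTGTCTTTGCTAGTTGAAGTGGGGAGTTCCGCGAAAATAATGCGGCAAAACAAACTCACGGTATGTGGCAGATT	0.817
GAGGCTATCTCTACTCATGAAAAGTATCAATGCGTATTTTACATTAGGGTAAGGATGCCATCGTAGTATCCACACTTAGTTAAGAGATACTCCAACTATACCACAGATCAAATCACTGTGACGCACGAAGCTCGCTCACATCATAAACAGTTCCCGTTCCACTAGGTACCAAGCTCGACACTTCCAAGGCTGGTAAACCATAACTGTCGCAGCACTCTCATTATCCTCTGCTCGGCGCAAGCATTTCGCGCCCATTCTTGATCCGTCCATAATATTTATTCAATCCGGCAATGCTATTCT	0.7937
CGTAATGAGTGCAGAGAATGTAGGCACCGCATCCGGGTGAAGGTTATGTGACTAATCGAACGACTCCAGTCTGTTAGCAACGTGGTTTGCGCGCTGGACGGTCCGCCCCCAAGCTGGCCAGGCGTCGAATTCTGCAGGTGCTGATACAGATCTGAGACCGCAATATCTGAGTCTGTGAGGGGTACTTTGCTTCACCGTGATAATGTCTCCCTGTAGGTTCAACGGTAGTCTCAAGTAGTTGTAGAGCACGTCGCAGGTGAGGACCACGGGGGAGCACGGTTGCACCCCATTAACATGGGC	0.8055
ATGNNNGCTTAA	0.5434
ACGTACGTACGTACGTACGT	0.5827
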