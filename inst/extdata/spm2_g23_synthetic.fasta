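>spm2_g23_synthetic stand-in g23 CDS with mcp-821F/mcp-966R sites planted at 748-893
ATGGTGACGTTTCAGTACACACCTGGTGTGGTCCAATCAACACAGACGGTTCCACGTGCTGTCTTAAAGCAGCGCACAAC
GATCAGGTCTCCAACTCGAAAATTAGGTATGAGTCAAATTAGCCTCCATGGTTCGACATTGCATCCTAGGCGATCTTTGA
CTGAAGCTACCCAACACGTGGCGCGTGCTTCCTCCTTCGCATTAGATCCGTTCGACAATGGTTACAAATCTATGGTGAAC
ACAAGGAGTTATCGGTGCCCATATAGCACCCGGCTAACGCGAGAAGTTTCTCGAGATTTCCCTCAAGTGCCTTCTGTTAA
AGACAAACCGACAGAGACAAACAGTCCTCGCTGGGCGGATCCCATACTAGATGGACGGCTGAGATATGAGCCGAGCGAGG
GTGTATCGCGGGACAATTTTTGGCTTTCTTATGACCTACGTAGCAGTAGTGAAATGGGCGAGCGGCAGGCCATACTGGTT
CTTGTCTCCGAAGTCAGCACGCTAGTGGATGTGGCTATCACTATTATATCCCATAATATCTCCCCAGGACTCACTAGTCA
CGGATGCCGTAAGTTTTTCGAACAAACTCAGCGAAGCGGGCTTACTGGATTCATCATACGCTACGAGCGAGATACGTACG
TGGTGTCTACCCTTCTTCGAGGTATGACGACCGATCGTATCAGGAGCGCAGGTATACTGGGCCGCATTGCAACACCATGT
CTGTATCTGTGGATCGGAGTGGGGGCACTGGCAGAGATTAACAGAGAAATATTAACGTGGTGCTTTATTGCCGGAATCAC
GGTCGAATCCGACCTATACTCATATAAGCAGTTACCTGCGGTCCGAGGACTCCGGGAGCCACAGCTAGATGTTGAAAAGT
TCAAGGGTCTCCTTGATGATCCAGACGATGGTAGGACGAGCCTCCCGACTCAGAATTTTCTTGTAGTGTGTCGACCTGAC
ACTGGTAGTACACCACTCGGGTCAGTGCGCATTTCTCATCCAGCTGGTAAGTGTCGAAATAGTTATCACCGTGCCAAGTG
TCCCCGACCGACAAGTCATCAGGATGGCGTGATTGGCCCGAGACCGTCCGTCAAGTACCAAGCTGACTCACTTTGCGCGG
CCTACGAGCAGACGTTCACCACTCGCGTTATCCGCCTAACAGAAGCGCAAAATGCACCGCCATGTGGTATGGGCCTTCGA
ATGCGGACAAGGATAAATCATAGAGGGTCAAGATCTATCATACCTAACTGGGGTATTGATTTCCGATTAATGGTCCGGCC
AAGCTATGATTACTCAGCCCGACCTCAGAGATACTATCCCCTCGTTGACTTACATGGGCCAAGTACTCACCTGCCTCCCG
TTCTGATTTACACGAGGGCTGCCGCCTACGTAACTGGTTTGCAGCGTGGGAACATGGTTGCACATGCCAGACCCTCCAGA
CAGATTAGTAACGCCCAGTTCAATTATGAATGTTCCATCTCTCTTAGTGTCTTTAAGTACGTGTGCCATTTTAGCGAGTA
A
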