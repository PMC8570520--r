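>synthetic_ref_1
GCAGCAGCAGCAGCAGCCGCGGCTTGCTGCTGCTGCTGCTGTGACGACGACGACGACGATGAAGAAGAAGAAGAAGAGTT
CTTCTTCTTCTTCTTTGGAGGAGGAGGAGGAGGCGGGGGTCACCACCACCACCACCATATAATAATAATAATAATCATTA
AAAAAAAAAAAAAAAAGCTACTACTACTACTACTCCTGCTTTTATTGATGATGATGATGATGAACAACAACAACAACAAT
CCACCACCACCACCACCCCCGCCTCAACAACAACAACAACAGAGAAGAAGAAGAAGAAGGCGACGCCGGCGTAGCAGCAG
CAGCAGCAGTTCATCCTCGTCTACAACAACAACAACAACCACGACTGTAGTAGTAGTAGTAGTCGTGGTTTGGTGGTGGT
GGTGGTACTACTACTACTACTATGCAGCAGCAGCAGCAGCCGCGGCTTGCTGCTGCTGCTGCTGTGACGACGACGACGAC
GATGAAGAAGAAGAAGAAGAGTTCTTCTTCTTCTTCTTTGGAGGAGGAGGAGGAGGCGGGGGTCACCACCACCACCACCA
TATAATAATAATAATAATCATTAAAAAAAAAAAAAAAAAGCTACTACTACTACTACTCCTGCTTTTATTGATGATGATGA
TGATGAACAACAACAACAACAATCCACCACCACCACCACCCCCGCCTCAACAACAACAACAACAGAGAAGAAGAAGAAGA
AGGCGACGCCGGCGTAGCAGCAGCAGCAGCAGTTCATCCTCGTCTACAACAACAACAACAACCACGACTGTAGTAGTAGT
AGTAGTCGTGGTTTGGTGGTGGTGGTGGTACTACTACTACTACTATGCAGCAGCAGCAGCAGCCGCGGCTTGCTGCTGCT
GCTGCTGTGACGACGACGACGACGATGAAGAAGAAGAAGAAGAGTTCTTCTTCTTCTTCTTTGGAGGAGGAGGAGGAGGC
GGGGGTCACCACCACCACCACCATATAATAATAATAATAATCATTAAAAAAAAAAAAAAAAAGCTACTACTACTACTACT
CCTGCTTTTATTGATGATGATGATGATGAACAACAACAACAACAATCCACCACCACCACCACCCCCGCCTCAACAACAAC
AACAACAGAGAAGAAGAAGAAGAAGGCGACGCCGGCGTAGCAGCAGCAGCAGCAGTTCATCCTCGTCTACAACAACAACA
ACAACCACGACTGTAGTAGTAGTAGTAGTCGTGGTTTGGTGGTGGTGGTGGTACTACTACTACTACTAT
>synthetic_ref_2
ATGAGCGCAAACGACCTATGCGGACCATACGAAGAAAAAGTATACCAAGAACAAGCACACGTACACGGATTCATACAAAA
CAGCGCACAAGGACACAGATACAGACACACACCAAACAAAGACATATACTGGGGAATACACGACATGGGAATGGTACCAG
AAAGAAGAATGGTACTAGACCTAAGAGAAACAATAGACCACTGGTGGTTCTTCGAAGACAGCATGAGCATGATATGGACA
TGGCACTACGTAGGAAGAGGACTAGCACTAGTAACAACAGGATACGTAGAAGAAACAGTACACAGATTCAGAACAAACGG
AATGAGATTCGTAAAACTAGTAGAAAGCTACGTAGACAACCTACTAATGGGATGGAGACACGAACTATACAAAATACTAA
GAAAAGTATACAGACTACAACCATTCTACGCAAAAATACACATAAGAATGAGCTACGGAGTATGCCACCAAGTAAGACCA
AGAGACCCACAATACAACCAAGAAGGACCACAAGGAGCATGGCCACTAGTAGTACTAGTAAGCAACCAATACTGGAGCGT
AACACTAATAGCAAGACCAAACCACGGACAACAACTAGGATTCTGGAAAGTAATAAAAAACGCATGGATGTGGGCAATAG
CAAGAAAAAGAGAAGCATGCTTCCCAATGAAAGGAATAGTTTGGCACTGGGACTTCCTAATGATGCCACAAAAACACTGC
TTCAAAATGTTCTGGAGCGGACACTGGATACACGGACTATACAGCATGATGTGGTTCAAACTAGACTGCTACAGCAACTA
CCCAGACCTAGAATACGGAAGAGGAGGAGCAACAGAAATGCACCACTGGCCAAAACAAAAAACATGGAACAGAAAAACAA
GCGAAATGGACAGCAAAGAA
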