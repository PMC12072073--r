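>synthetic_rRNA_28S_like
AGCGGCTGTCTACGTGAGTGGCTGCGGATCAGCCTACGCCCTGGGGATATATAATAGATGAAGCAGGTAT
CCAGGCCGCGCGGCCTCTCAATCACGCTAACAAGAAAGTCGACGGTTTTCTGCCCCCCCACTGCAGATAG
CACCCTTGACCCGGGCGATGCATTGCGTCGCTGCCGCGACGAGTAGCAATACAAAGCACGGTTGTGTACA
TGCGGCGAGGGCACCCCATTAGAACCAACGCGAGCGAGAACTTCACGGGTCTATGATTTTTGATATCATC
TCCGTGCCCCCCCATCGTTACCGCACCAGTAAGGATACCTCGAACATCGAAATGCAGTGCTATTACAGAT
TACCGTGCGTGTAGCGACGCTCGCCCGTAGTATCTTCTCACTTTGACAGCGCGGCGTTGTGGCTTGTTCA
ACTTCCACGCTGAGATGTCAGGCCTGTCAGACGAGGTGGACGTCGCCAGGCCTCTGCGTCTCTGTGGGGG
GGGATCTACCCGAATCCCACGTTGGAACCAATGGGGTACATATGGGAGGGACTATGAGAACCTTCATGTT
TCAAGAGTAGACATTCAGCGATTAGTAAGCCCGCATACCCGCTAGACACCGGGTTGGTGTGGGGTAGGAG
GCTTGCGTGACACCGTTCGGCTGATACTGGACTATGGACCAATTTACTCAGGGAGTAGCTAGAGCGGATT
TGAGCGGGTAAGTACCGCGAACCGCATCGCAAACGTCTCCCTGGGTGGCCGCGCCAAAGCCACTTTTGAG
TATCCTTTAGATACAGGGTCTTGGGGTAGGTGCTTTAGACAGAGCGTACCCTGAGACGAGGCCGCAGCTC
CGACCCGTAGGTCGAAATTCGTCACGCTTCTCGCACCCGTCCTCCCCTTTATGAGTCAAGCTAGGGCCTT
CGGGCGTGAAATCTTGGCATCGGTAAATTTGGGTGACCCTTTTACCAGAGACTAGCTGTGTAGTTGTGCG
TACACCCCATTTCACGCGCAGATATATACCCCCCAGTTTCGGACTATCTGGCAGCTGTCCTTCAAGATGT
TGGGATGGTCCCTGCATCCCTTTCACTTTCCCTGCGGATACATCTTTGTCAGGTAGTTGATTGTGGTGCC
AGGGACCGTACGAGTCAGGATCCTGCGATCTGTAGATTGGCGAGACGGACGAAGTCACACGACGAACTAG
AGGCCCCCTCTTGCGGCTGCCACGACCCCATCACGCAATTTCACCCGTCTTGAGTGGGCTAATTGCGGCC
AAGAATGCACGTATCAAGCTGCGCATTGGACAGACGCCATCTACACTGTACCACACACTCGTCGATGGGG
TAAACTACCCCCTTTTTAGACAAAATCCTCAGGGTAGCTGACCACACGACGCTATCGGAGGAACAGCTTC
GACGGGTCCAGCCACCGAGGAAGCGACGGAGCGATACTGTCCAGCGGAGCGTGCAACGGCGGACAAGGCG
TGCCCCGAGTTAATGAGCCCATCCGGTGCCTCTTCCAGTCATGACTACAAGTCTGCCGGGCCCAGCCTGT
GCTGTTAAAGACGCCAGAAGGGAACCGCGTTGCCGATCACATAAACCCACGCCAAGTTCATTTTAGGAGC
TAGGGGATCCCCTTCCCCGCCAAGACAGGGTATGTTGTTCCCGCTTAAAGGGGAAGAGAACTAGCGCTTA
GACGGAGATATTTGCCCGTAACCGACTGAGGCAGTGCAGATCAGTCGTTCGGTTGATTCACACTGGTAGG
AGACGGGGGGGAACTTACTCAGCCGGCCACGAGTTAAGGGAATGAACTGG
>synthetic_rRNA_18S_like
ATGGCTTAAGTACCGATCATTCCCCTTAGGCCCCCGTAGATATATGATCAGGAGCAAAGACCGTCCTAGG
GACCGGCCCGTTTGACACCCTATCATTCAATATCAGGGAGCGAGACGAGGCCTTCCCCGAAGGCAACGCC
TACGGTGTCGCAGCCCGTAACGTCATCGGTCAAAGAGGCCCGACAGGCGCGTTTTGTTGTTAGAACGAGC
TCCAGCGTGGACGTCGTCTTCAATGACTCGGGAGCCGGAACGGCAGTCAACACGCTTGTGCTTACTACGC
CGTGTATTGCTAAAGCTTTCGGTTATCGTGGTCATCCGTCACTTTGGCTCCTGCTTACGTGAATTTAGGA
GCAATCGCGCGAGCCGGTAGTGGACCCGTTCCTCGAGAGTAGCGATACTGGTCGTCTCAATCAGTAGGCA
CACCGAATCGTGTGGCGACGTCATCTCGGGACCACGCATGCTCAGCCCCGCTGCGTCGGCATCAGGGTAC
TTATGCCACAGGCAGCCAGGACCTCGCTAAGGTGATAGAAGCCCTAGCTAGAGGCTAGCGTCGCTAGTTC
ACGCGCGTTTGAGTCAATAGCGTCAGACGGCCCGGACGATTTCGAAGCAGCCATTATCCCTATTCTAGGG
CCTCTGCGCCCATCCAATGCGTGCAGCGCTCGCAAACAACCCCGGGCGGGATAGACCGTGCACGGTGGAG
GGTCATCGTAATTCGTCTAAGTCCTAGGTGCACGCGACCTGACACGATTTGGTAAAATACGCACAACACG
GAGGCGTAAGCCCGAGTTGCGAGGTCAGCATTCTCCAAGTTCTAGGGGTACAGAAGTATTTTTCGGCCGA
GCGCAGATTATGGCGCACGGCTTGGTAGGTCGTATGTCGTGACGGGGATCGGTGCACACCTGACATCATA
GGATCGTGGACTCGCGCTAGTGTGCGACACTTGTTAGTTTATATGTCTCGCAGTTCCCGTGCTTCCTACT
GCCCTCTCCCACCCCTACGCCCCGCTAAAACAGCTGCGCTTTTACTTCATGGTCTGTGGAGTTGCAGCAG
CAATCTCACTACCGTCACAGAGGGGAACCTAGTGCTGACAAAAGCCCGCACGGCTCCGTCCGAATGTAAT
AAGGCGGAGAGGGACTGTCCGGCGCTGTCACCAAGTACTGTCCCGACTTGCCACGAATGCTGACGTTTAT
CGCTAACACCCTCACTTCACTCTCCGGAACCCGGGTTGCAAGCGAGGCGTACTCGCTACCAGGAACGGCT
ACATCGGGGTGCAGAGATCGCCGCCCCGCTTATCAGTCGCTCGCGGCTATTTTTGGGTACTAAGTCGTTC
TCCGACTAGTGCGGTTAGGCTCCCGGTCCGTATTACTTTCGCTCCGCCTTGCGTTTATCTAAACTTAGGA
ATAGCAGGAAACCTCGAACGCTTCCTGCTGGCAATTAACTTCCAAACTGTTGCGTTAGGCCATCCACGGA
CCCGACGACGCGACAACTATCTGGCACAGA
>synthetic_tRNA_1
AATTGTGCGCCTTCGGCGAGAGGTCTGCAATCTCCCGCGTGTCATATCTTTAACACAACTAGCTCATTGA
ACGAT
>synthetic_tRNA_2
AAAATTCGGATAGACTATGGTGGTGTATCAAGATCGCGGACAAGGAGCATGCCCGCTCCAAGCATGCCTA
GCCCG
>synthetic_tRNA_3
CAGATGAAGGCGGAACGTTCGTTCGCCAAACTAACGTAGATTTACAGGGTTCAAACTCGGTTCGTGCAAG
CGGCA
>synthetic_tRNA_4
CCAGAATGCTGCTACCACACATTGTTCAACTGGATGATTTCGATCATAGATATCAATGGAATGAAATGGG
TGTAG
>synthetic_tRNA_5
CATGATACACCACGTGATCCCATGCCTACCAAGCTCTGAACCTCAATTGGAGCATTCTGCTTAGAACACG
GTTGG
>synthetic_tRNA_6
GTGGCGGTGGACCATTACCGTAGGTTGACTTAGGGGTCTCTAGGAACATGCTGTCAGCTGTCTGATGGGC
TTCGT
>synthetic_tRNA_7
TAACACTGTTCACTTGCAACCTCCTGCATCGATGCTCGTCCTAACAAACTTAGTTAGATGGTTCATAAAT
CTCCT
>synthetic_tRNA_8
ATGGGCCAGAGAACGATCATCGGCGTTGTCGGTACTCCAAAGTACGCTTCCTAGGAAGGCTTCGTAGCGG
TTCTA
>synthetic_snRNA_1
GTTTCGCGGTGCCCTAACAACCCGAAGCCTTTACATTTTAATGCTATGAGGATGCTACGCAAAATTAGTT
TAGGTTAGGAACGTCCTGCGAGGATTAAACCCCATCAGGCCCGAGACCATAGCCATGAAGGCCATCTGTA
CGGGCTTGTA
>synthetic_snRNA_2
ATATACCAAAACTGACTCAGCGCAAGCCACCTAGTTAGTCATCAACTGCACCAGTATGATAAATCTTCGA
GAATTTCATAGTCCACTGAACGTTGACATGCCCTTCTGCATCATTGGACTTCAATCGATCAATTTGACTG
CCGCTTGAGG
>synthetic_snRNA_3
ATCTCCCCGTTTGGAGTCCCACGATGCAAGACTCCGACTTAATTACCCTACATGTTGACGGTACTGTCTA
GCGTGCCCTTCCGAAATTTTTGGGTACGTTTACATTTGATCTTCGGTATCTCCTTCTGTGCACGAGAGTA
TAAATCTTGC
>synthetic_snRNA_4
ATCTATGTCACATACCCCTCGAACATAATGTTGATTAGAAATAATTTCTTCATATATGGATGCTCAAGGT
AATAGGTCGGTAAAGAGAGGTCGTGCCCGCTGACTCTGACTTAATGTTTTATAGTGGTAGTCAACTCAGC
AATTCTCGAC
>synthetic_miRNA_hairpin_1
TCTTCCATCAATCCGAGCAATTATACACTCCGATAGAAACATTGTTGGATAAATAACGGGAGTCTGTTCC
>synthetic_miRNA_hairpin_2
AAATCAATTAATCTCTTTTTAGATCAAGTTTGTACATGGTTTTCTAATTGCACACCGGCATATCTAGTTC
>synthetic_miRNA_hairpin_3
AAGATAGAGAACGATTTTATCTTAATCGTTTGACAAATATAAATACATGATAGCTTAACGGTATCTGTCC
>synthetic_miRNA_hairpin_4
CAATATCCGTTAGAGAATAGGCTGAAGATATTGACTTCCATAGTCTTTTGTATTATACCGCTTACTGTAG
>synthetic_miRNA_hairpin_5
CGTTCGATAAACAAAGATAGCGATAAGTGGATGGAGAGGGACACCCTGTTTACCGATGTTTATTATATTG
>synthetic_miRNA_hairpin_6
GGTACTAATGACAGAGACAAACTCCTCCTGGTGATCGGGAATGTCAGGTGTGAGGAGTACCGGAGTAGTC
>synthetic_miRNA_hairpin_7
GCCCATAGCCGGTACTCGCAGATGAACCAAAAGGACAGAGTTCATTCATAACGAAGAAATTAAAGACGAC
>synthetic_miRNA_hairpin_8
GTCGTTCCCTAGTCTGGCTCTCCCTGAATGATGTAGATATATAAATCTATGCCCCACTCTGCCCCACGCA
>synthetic_miRNA_hairpin_9
CGGTCTCAGATTCTCAAGAAAGAGACAAGAGGCGATTGTTTGCAATTCTTTGCTTACGCCCACGTACATA
>synthetic_miRNA_hairpin_10
TCAAAACTTAAATTTTCGGCAACGGTCCCCTAAGAGCTTGTAACACGAGTACTTTTCCACTCCCAAAGGT
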