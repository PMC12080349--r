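>ctg_L0001
CAAAACTTCAGTTATTTTATAAACACATAACTTATCAAGACTGCGTATTTTGTCGAGGATGAATTGGAAGAACTATGCTG
CAGCAGCACTAGCATTAAAAGACTTCGATCAACTATCTGCCCGTCAGAATTGGAAGAACTATGCTGCAGCAGCACTAGCA
TTTTATATACTATAACGGGTATACAGTGTAGAGAATTGGAAGAACTATGCTGCAGCAGCACTAGCATTGGTGCTCCTAAC
CTCGCTATGAGATAGTGTGAATTGGAAGAACTATGCTGCAGCAGCACTAGCATTTAATCCAGTTTCTTCGACCATTCAGC
ATCAGAATTGGAAGAACTATGCTGCCGCAGCACTAGCATTTTACAATTCGTTGCCTACTACCCACTACTTTCCGCCTAAT
GGGTAGTAGTTTAAACGATATCCACTGGATGCCCATAAAACAATCTATTAAAAAAAACCTCCCCGGAAAACCGGGGAGGA
ACATTATAAGAATTGCTTGTCCTTCCTCACTGCCATAGCAATGTTCACTAGTCTCTCGAAAAGGCTCGGGGCGACGCATC
TAATCGGCGTTATGCGATAGGGAACCATGTGGAGTCTGTCTTCTGAAAGTACTGGAAGAAAAGGAGATCAAGGCGACTTA
TGATAGTCATAGTAGGGCACTCATGGATAAGTGGGGCTAATGGTGGGTGGTTCTAGTCGCTAAGTCTTAATGCAGCCTTG
CACACGTAGCTCGCTTGGTCATAAGTCAGGCTGGTCTACCATTCCGCCTCGAGTCGTCCGTGGTGATAACAAGTGGAACG
GTGATCTAACTTCAACTATGTGATAGCTAGGACAATAATGCCCCGTTACGGGGGCATAATAGAAGCCACCTTTTTGCCGG
CGTACCGAATCGGACATCAGCT
>ctg_L0002
AATTTAATATTTGCTTAGTACTCAAAGTTAAAGGGAGTTTACACGGACAAAAGTCAGTCGGGATAGTTATGCCGGGCATC
GGCTAGATTAGCTAAGGACATCCCGAATCATACCCAAATAAATGTTGGATAGTTATGCCGGGCATCGGTTAGATTAGCTA
AGTTAAAGGTCAATTGTCCATTATATCATCCCGGATAGTTATGCCGGGCATCGGTTAGATTAGCTAAGTACTGCGCCACC
CTAGGGGGCACTTGTGATGGATAGTTATGCCGGGCATCGGTTAGATTAGCTAAGGATGACTTTGATTGTTGATCCATGAA
GTTGGGATAGTTATGCCGGGCATCGGTTAGATTAGCTAAGATATCAGTTGGTTAACTGGTTGAGCCCAGGGGATAGTTAT
GCCGGGCATCGGTTAGATTAGCTAAGGCCAATCAGCATCCTATATTAAACATATCAGGATAGTTATGCCGGGCATCGGTT
AGATTAGCTAAGGCCCCCGACGTGAGGTTAACGGTCAATAACGGATAGTTATGCCGGGCATCGGTTAGATTAGCTAAGTT
AATTCACATCCTAGAGCTTTCGTTCCAAGATTTAATCTACGGATGTGAATCAGGCTACTACCTCTAGGCCTTTTATATTA
ACACTCACTTATCAGGTTACGGCCGTCAGAGTTTTCTTCTTATAAAAAAAACGGCGCGGGCGTTCCCGCGCCGTCCAGCT
ACTTTTTCGTCTCAATGATAAAGGTGATAGATTAGGTGAATTTATCACCATATTAAGTGAGTGAATTCAATAATGCCCCA
CTATATCAAGAATTATAATTTGGAGGTCCAATCCATATTATCCTACAAACCCGGACGACCGTCAGACAAGGGCAGTCTCA
TCCTCGTGTCGTAAAGGGCCTGCCATCACGGCATCAATTGTGTCGATACCAAGCAAAACCTTGCACGTATATACTGACGA
TCAGAATGGGCAGAATATCGAGTAGAGGGTAACTATGATTCATGAGTATACAAGCATTCTGCCAGTATTGAGAGCTCTGC
AACTCACAGGTAAACTGTTCGTTGTCGTGTTGACAATTGATGTTTGAACTTTATCTGCATCTGGGCAATAAATCCTGAGG
TAGCGCTATTAAAGGAATGATCTCGCTTCGACAGGCAGACGCTAATAAGTGATTT
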