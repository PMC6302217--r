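motif_id	consensus
1	AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTG
2	CACTCGGCCTTTCCATATCTCGTGAACCCCCTGCA
3	CGCCCTAAAGTACAATTAGGATATTCATCCCTACA
4	CTGTATATGCCGAACGTTCTAATAAACGACTTAGC
5	AACAAGTCGCCTAGAAAGGTACCGCTGGCATATCA
6	CGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCT
7	CGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCT
8	TTGAAACAGCTGAATAAATCGTGTGAATACGTGAG
9	TCGTCGGAAAGCAGTTGAATATCTAACGACCCCTG
10	CGCAAGGACACACTAGTCGCCCTTGAGAGCACTCC
11	AGTCCAGGCGAGGTATCCACGACGATACGACTCGG
12	CTAGCAAACGCGCGGTTTATCTATGCAGCTAATAT
13	CCTTAGTAGTCGACCCCTGAGATGACCGGTCATCA
14	GGCGGCATCCGACGCACCAACGGCTCCTACAGACT
15	CGTGCTACCGGACCATGCGACTCGAACATCAGATG
16	GACAGACCTCGTAATAGCCGGGCCATGTAACACTG
17	ATGTCTCCGGGCAGCTCATGACGAGCACCAGACCC
18	GAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAACG
19	CTATCGAGCGCGTAAGCGCCAACCCGCATTTACGA
20	AGTACCCATCGTATGTAATAAGACCTCGAGTACGT
21	CGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGT
22	TCGACGTTGCCGATGTTTACCCTAAGGGAGACGAC
23	ATCATCGCACGACTCGTCATTTGCATCATCTCCAC
24	TGCCCCGATGTCTGCTATGGACGGCTTCACCTGAT
25	GTGGAGCGAGGGTACTGATAGATATACGACAATGC
26	ACGTAGTCTCGATACGTCATTGGTACGAACAGTTC
27	GTATTCCCCATGTCTGGACCGACGTTAAGCTCATG
28	TCTCAGGACGGAGAATGCAGCCCAACAGCTTGGCC
29	GGATCAAGCAGGATGAGAGGCACTTACTTTCCCCG
30	CTACGATGCTTTGCACAAATTCTACCGCATTGATC
31	GTGGATTACTAGTTTTGATGGCATGGGTAATGGTG
32	GAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGC
33	CTACGTGGAGTCTCTGTGAAATTCAGAGATACGCA
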