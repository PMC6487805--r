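CLUSTAL multiple sequence alignment

G1—gene1—S1   AGTCCCCAGGCTAAACCGTCTGAATACCGTATGTAACCAGTATCACCGAGACTTATGCGC 60
G1—gene1—S2   AGTCCCCAGGCTAAACCGTCTGAATACCGTATGTAACCAGTATCACCGAGACTTATGCGC 60
G2—gene1—S1   AGTCCCCAGGCTAAACCGTCTGAATACCGTATGTAACCAGTATCACCGAGACTTATGCGC 60
G2—gene1—S2   AGTCCCCAGGCTAAACCGTCTGGATACCGTATGTAACCAGTATCACCGAGACTTATGCAC 60
G3—gene1—S1   AGTCCCCAGGCTAAACCGTCTGAATACCGTATGTAACCAGTATCACCGAGACTTATGCGC 60
G3—gene1—S2   AGTCCCCAGGCTAAACCGTCTGAATACCGTATGTAACCAGTATCACCGAGACTTATGCGC 60

G1—gene1—S1   AGCAATCTTGCATCATTGTTATCGAACGGAGCCGGTAGGAAGTACAGGACGTTGGGCAAG 120
G1—gene1—S2   AGCAATCTTGCATCCTTCTTATCGAACGGAGCCGGTATGAAGTACAGGACGTTGGGCAAG 120
G2—gene1—S1   AGCAATCTTGCATCATTGTTATCGAACGGAGCCGTAATGAAGTACAGGACGTTGTGCAAG 120
G2—gene1—S2   AGCAATCTTGCATCATTGTTATCGAACGGAGCCGTAATGAAGTACAGGACGTTGGGCAAG 120
G3—gene1—S1   AGCAATCTTGCATCATTGTTATCGAACGGAGCCGGTATGAAGTACAGGACGTTGGGCAAG 120
G3—gene1—S2   AGCAATCTTGCATCATTGTTATCGAACGGAGCCGGTATGAAGTACAGGACGTTGGGCAAG 120

G1—gene1—S1   GCCTACCAGCAAGTGCCTGGCGAAGGACGTTAAGTTTGAGGAAAGCACAAACGTACCGTC 180
G1—gene1—S2   GCCTACCAGCAAGTGCCTGGCGAAGGACGTTAAGTTTGAGGAAAGCACCAACGTACCATC 180
G2—gene1—S1   ATACCATGGCAAGTGCCTGGCGAAGGACGTTAAGTTTGAGGAGAGCACAAACGTACCATC 180
G2—gene1—S2   ATACCATGGCAAGTGCCTGGCGAAGGACGTTAAGTTTGAGGAAAGCACAAACGTACCATC 180
G3—gene1—S1   ATACCATGGTAAGTGCCTGGCGAAGGACGCTAAGTTTGAGGAAAGCACAAACGTACCATC 180
G3—gene1—S2   ATACCATGGCAAGTGCCTGGCGAAGGACGTTAAGTTTGAGGAAAGCACAAACGTACCATC 180

G1—gene1—S1   CAAGGACTGGTGCTTGCGTG--------CATTTTTCCGACGACTTGGTCGATTTAGTTAC 232
G1—gene1—S2   CAAGGACTGGTGCTTGCTTG--------CATTTTTCCGACGACTTGGTCGATTTAGTTAC 232
G2—gene1—S1   CAAGGACTGGTGCTTGCGTGAACCTAACCATTTTTCCGACGACTTGGTCGATTTAGTTAC 240
G2—gene1—S2   CAAGGACTGGTGCTTGCGTGAACCTAACCATTTTTCCGACGACTTGGTCGATTTAGTTAC 240
G3—gene1—S1   CAAGGACTGGTGCTTGCGTGAACCTAACCATTTTTCCGACGACTTGGTCGATTTAGTTAC 240
G3—gene1—S2   CAAGGACTGGTGCTTGCGTGAACCTAACCATTTTTCCGACGACTTGGTCGATTTAGTTAC 240

G1—gene1—S1   AGTCGTGATCGGCCTTGAAAATCCCGAATAGTATACCGATACGGCACCTAGGCTCCAAGC 292
G1—gene1—S2   AGTCGTGATCGGCCTTGAAAATCCCGAATAGTATACCGATACGGCACCTAGGCTCCAAGC 292
G2—gene1—S1   AGTCGTGATCGGCCTTGAAAATCCCGAATAGTATACCGATACGGCACGTAGGCTCCAAGC 300
G2—gene1—S2   AGTCGTGATCGGCCTTGAAAATCCCGAATAGTATACCGATACGGCACCTAGGCTCCAAGC 300
G3—gene1—S1   AGTCGTGATCGGCCTTGAAAATCCCGAATAGTATACCGATACGGCACCTAGGCACCAAGC 300
G3—gene1—S2   AGTCGTGATCGGCCTTGAAAATCCCGAATAGTATACCGATACGGCACCTAGGCTCCAAGC 300

G1—gene1—S1   GATACCTACAGAGCAAGGCTCAACGCCATGGATATCGGCGCCAATCCACAGATGATGACC 352
G1—gene1—S2   GATACCTACAGAGCAAGGCTCAACGCCATGGATATCGGCGCCAATCCACAGATGATGACC 352
G2—gene1—S1   GATAGCTACAGAGCAAGGCTCAACGCCATGGATATCGGCGCCAATCCACAGATGGTGACC 360
G2—gene1—S2   GATAGCTACAGAGCAAGGGTCAACGCCATGGATATCGGCGCCAATCCACAGATGATGACC 360
G3—gene1—S1   GATAGCTACAGAGCAAGGCTCAACGCCATGCATATCGGCGCCAATCCACAGATGATGACC 360
G3—gene1—S2   GATAGCTACAGAGCAAGGCTCAACGCCATGGATATCGGCGCCAATACACAGATGATGACC 360

G1—gene1—S1   TGACGTACTCCCGATTCCAAGCACCGGCCTCCTTCGTTTCTCCGTGGTCACGCGCTATAC 412
G1—gene1—S2   TGACGTACTCCCGATTCCAAGCACCGGCCTCCTTCGTTTCTCCGTGGTCACGCGCTATAC 412
G2—gene1—S1   TGCCGTACTCCCGATTCCAAGCACCGGCCTCCTTCGTTTCTCCGTGGTCATGCGCTATAC 420
G2—gene1—S2   TGACGTACTCCCGATTCCAAGCACCGGCCTCCTTCGTTTCTCCGTGGTCATGCGCTATAC 420
G3—gene1—S1   TGACGTACTCCCGATTCCAAGCACCGGCCTCCTTCGTTTCTCCGTGGTCATGCGCTATAC 420
G3—gene1—S2   TAACGTACTCCCGATTCCAAGCACCGGCCTCCTTCGTTTCTCCGTGGTCATGCGCTATAC 420

G1—gene1—S1   GCCTGATGGTTGATTTGAGAGAATAATCAGGAGATAGATTCGATCTCCTAGTAAGGATTG 472
G1—gene1—S2   GCCTGATGGTTGATTTGAGAGAATAATCAGGAGATAGATTCGATCTCCTAGTAAGGATTG 472
G2—gene1—S1   GCCTGATGGTTGATTTGAGAGAATAATCAGGAGATAGATTCGATCTCCTAGTAAGGATTG 480
G2—gene1—S2   GCCTGATGGTTGATTTGAGAGAATAATCAGGAGATAGATTCGATCTCCTAGTAAGGATTG 480
G3—gene1—S1   GCCTGATGGTTGATTTGAGAGAATAATCAGGAGATAGATTCGATCTCCTAGTAAGGATTG 480
G3—gene1—S2   GCCTGATGGTTGATTTGAGAGAATAATCAGGAGATAGATTCGATCTCCTAGTAAGGATTG 480

G1—gene1—S1   TCCCTCCATGCTATGTGTCTATGTTCGAGGCTGCTCTCGTTATTACTTGAAGTTAGTATG 532
G1—gene1—S2   TCCCTCCATGCTATGTGTCTATGTTCGAGGCTGCTTTCGTTATTACTTGAAGTTAGTATG 532
G2—gene1—S1   TCCCTCCATGCTATGTGTCTATGTTCGAGGCTGCTTTCGTTATTACTTGAAGTTAGTATG 540
G2—gene1—S2   TCCCTCCATGCTATGTGTCTATGTTCGAGGCTGCTTTCGTTATTACTTGAAGCTAGTATG 540
G3—gene1—S1   TCCCTCCATGCTATGTGTCTCTGTTCGAGGCTGCTTTCGTTATTACTTGAAGTTAGTATG 540
G3—gene1—S2   TCCCTCCATGCTATGTGTCTCTGTTCGAGGCTGCTTTCGTTATTACTTGAAGTTAGTATG 540

G1—gene1—S1   AGTTTCTGGATGGCATTACGCGGCTGCTACTTACAGGTCTACCGTCTGTGGTTACGCCAA 592
G1—gene1—S2   AGTTTCTGGATGGCATTACGCGGCTGCTACTTACAGGTCTACCGTCTGTGGTTACGCCAA 592
G2—gene1—S1   AGTTTCTGGATGGCATTACGCGGCTGCTACTTACAGGTCTACCATCTGTGGTTACGCCAA 600
G2—gene1—S2   AGTTTCTGGATGGCATTACGCGGCTGCTACTTACAGGTCTACCGTCTGTGGTTACGCCAA 600
G3—gene1—S1   AGTTTCTGGATGGCATTACGCGGCTGCTACTTACAGGTCTACCGTCTGTGGTTACGCCAA 600
G3—gene1—S2   AGTTTCTGGATGGCATTACGCGGCTGCTACTTACAGGTCTACCGTCTGTGGTTACGCCAA 600

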