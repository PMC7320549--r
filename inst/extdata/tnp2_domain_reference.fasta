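>tnp2_domain_reference synthetic 630 bp tnp2 transposase domain reference (diagnostic motif at 159-174)
TAGAACAGAGAGTGTGCTTAACTCGCCGTAAGAAGGTCTTGGTAGTACGTATCGCGCCTT
GTCATATTCCACGAAGAATCATTATCAACGGGTTTTAAGAAATCTCCCACGTAACTTTAA
GTAGATAAATCAGAGTGCCTTTTAACTATCTTAGATGTTATAACTTGCCTCCTTCCAGAG
TTAGTAGTACTCGAAGGTAGGATGACTCATAGGGTGGTCAAGTATGCATAAAGTCTAACA
CACGTATTGTGTACAGGTATAAGTTGTCTGCTCCTAGAGATATCATCTGTCCATTTGATG
CGACAGCTGCAACAAACCTGGGTAATATCAAATTTATGTCTAAACATAGTAATTGTGTTC
ACCAATCACCTGTCGTAAGTATTATGTACATTAGGTTAGCAGGGCTCGTCACCGATGGGC
GTTTGAGAATACTTCTTTTTATGCCAGTTCGCCGAAAGATTTCAGGCCAAGTCAATAAGA
TGGATCAGTTCCAGATAGCTGTTTAACGTATGGCGCGGCACAACTGACTAGTCAGCACGT
CTTGAAGTGATACCTGTTATTTACACCGTTCGGTTACTTTACACATTACATGGCTAAAAA
CCATTTATTCGAGATTATAGCGGAGGTGAT
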