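>ltrB.NheI.S
CTAGCGCTATATGCGTTGATGCAATTTCTATGCACTCGTAGTAGTCTGAGAAGGCATATG
>ltrB.BstAPI.AS
ATGCCTTCTCAGACTACTACGAGTGCATAGAAATTGCATCAACGCATATAGCG
>ltrA.XhoI.S
TTTCTACTCGAGGCGTTGATGCAATTTCTATGCACTC
>ltrA.BstAPI.AS
GGCATCAGAGCAGATTGTACTGAG
>del-Pptb.S
GGGGTTAATCATTTAACATAGATAATTAAATAGTAAAAGGGAGTGTCGAGATATCC
>del-Pptb.AS
TCGAGGATATCTCGACACTCCCTTTTACTATTTAATTATCTATGTTAAATGATTAACCCC
>MfeI-BstAPI.S
AATTGATTTAGTAATTTCTATAAGCAGGTTAGCTGTAAAACTAGCAGTAGCACGCATATG
>MfeI-BstAPI.AS
ATGCGTGCTACTGCTAGTTTTACAGCTAACCTGCTTATAGAAATTACTAAATC
>NheI-MfeI.S
CTAGCATTTAGTAATTTCTATAAGCAGGTTAGCTGTAAAACTAGCAGTAGCACC
>NheI-MfeI.AS
AATTGGTGCTACTGCTAGTTTTACAGCTAACCTGCTTATAGAAATTACTAAATG
>NheI-SacII.S
CTAGCATTTAGTAATTTCTATAAGCAGGTTAGCTGTAAAACTAGCAGTAGCACCCGC
>NheI-SacII.AS
GGGTGCTACTGCTAGTTTTACAGCTAACCTGCTTATAGAAATTACTAAATG
>frag1.BglII.S
GGGATATGATATACGAGTAAGGAGATCTGG
>frag1.EcoO109I.AS
AGTATTAGGCCCTGACGTCCCACATAATTCACAACATTTAGC
>frag2.BglII.S
AACAGGAGATCTGCTAAATGTTGTGAATTATGTGGGACGTC
>frag2.EcoO109I.AS
TACTCTAGGCCCTGGAGACCCCACACTACCATCG
>frag3.BglII.S
TCGCCAAGATCTCGATGGTAGTGTGGGGTCTCC
>frag3.EcoO109I.AS
GTGCCACCTGACGTCTAAGAAACC
>SOE3prime.S
TGGGAAATGGCAATGATAGCGAAAC
>SOE.EcoO109I.AS
ATAGGCGTATCACGAGGCCCTTTC
>gBlock.BglII.S
CGAGTAAGGAGATCTGGAACGATAAAACG
>CpaAII-anneal.S
CTAGAGTCGACGTCACGCGTCCAAGGAGATCTCCAGGCCTGCAGACATGCA
>CpaAII-anneal.AS
AGCTTGCATGTCTGCAGGCCTGGAGATCTCCTTGGACGCGTGACGTCGACT
>SYCP.gBlock.S
GGAGGTCAATCTATGAAAATGCGATTAAGC
>SYCP.gBlock.AS
CTTTCGTTTCGTTCCCATAGGTTCTCC
>MTLCP.REN-HindIII.S
GTATTTAAAGCTTATAATTATCCTTAAATTTCTTAAAAGTGCGCC
>REN.Fw
CTACTTGAGGTCTAGGACTTCTATCT
>REN.Rv
ACAGATAGGCCATTAAAGGTATTCA
>ltrB.Fw
CCAACGCGTCGCCACGTAATAAAT
>ltrB.Rv
ATGGGAACGAAACGAAAGCGATGC
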