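>Vssc_synthetic_cDNA synthetic reference (seed 20230901)
TCACTTTCCTTTCAGCTCAGCCCAGTCCGGAATTGGAGAAGGTGCGCTTAACACTCCAATTTACTCATTTCGATTATGAG
AGGTGCTAAAGGTGCATTGGGTAATCTGACACGCCCGGTAAAGTGGGTGTAGTCTGTGTGGCGGGGTGGCTCATCTGGGG
TTCATCAAAGGATCGCTTCAAGGACCATGAATGATAAAAAAGAACCGCGCGGTAGTCTCATACCCAAACTGTTAACGGTC
TTGTGCTCAGCAATCGGGTCGGACGAATTAGAGGCGTCAGCTATTATTGCCACTGATCCAAGACCCAGGCATCCGAACTC
GAAGAATTGGATGCCGCACGGAAAAACGGTCGTGATCGGCAATCTTGTGGTAAGTTGACGCGGCGGCAGGCCATTAGACA
AAGTATACTCATTGTCCACGGGCATTACAAGCAGTTACGGTGGGCTGAGAGTTTCGTTCTCAGTGACGCAGTATTGCCAT
CGTTAAATTTCCTTAAGCCCCCGTTCTTTCGGCTTAATACGGCTCGTAGATTTCAGTAGTCCTATTCAATATGTGTTAAC
TATTTCCCACTGTTCCCGTTGGTATTATTTGTATGAGTCCTATCGATGAGTTCAAGCCTCGACGACTCGTTTTAAGAACT
GGGTGAAACGTAACCAGTCGCATGCATTAATCATGGGCGATGGCTTGAACAAGTCTCTTATGATCCTCGGTGC
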