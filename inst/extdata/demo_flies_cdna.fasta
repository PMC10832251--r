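>fly_01
TCACTTTCCTTTCAGCTCAGCCCAGTCCGGAATTGGAGAAGGTGCGCTTAACACTCCAATTTACTCATTTCGATTATGAG
AGGTGCTAAAGGTGCATTGGGTAATCTGACACGCCCGGTAAAGTGGGTGTAGTCTGTGTGGCGGGGTGGCTCATCTGGGG
TTCATCAAAGGATCGCTTCAAGGACCATGAATGATAAAAAAGAACCGCGCGGTAGTCTCATACCCAAACTGTTAACGGTC
TTGTGCTCAGCAATCGGGTCGGACGAATTAGAGGCGTCAGCTATTATTGCCACTGATCCAAGACCCAGGCATCCGAACTC
GAAGAATTGGATGCCGCACGGAAAAACGGTCGTGATCGGCAATCTTGTGGTAAGTTGACGCGGCGGCAGGCCATTAGACA
AAGTATACTCATTGTCCACGGGCATTACAAGCAGTTACGGTGGGCTGAGAGTTTCGTTCTCAGTGACGCAGTATTGCCAT
CGTTAAATTTCCTTAAGCCCCCGTTCTTTCGGCTTAATACGGCTCGTAGATTTCAGTAGTCCTATTCAATATGTGTTAAC
TATTTCCCACTGTTCCCGTTGGTATTATTTGTATGAGTCCTATCGATGAGTTCAAGCCTCGACGACTCGTTTTAAGAACT
GGGTGAAACGTAACCAGTCGCATGCATTAATCATGGGCGATGGCTTGAACAAGTCTCTTATGATCCTCGGTGC
>fly_02
TCACTTTCCTTTCAGCTCAGCCCAGTCCGGAATTGGAGAAGGTGCGCTTAACACTCCAATTTACTCATTTCGATTATGAG
AGGTGCTAAAGGTGCATTGGGTAATCTGACACGCCCGGTAAAGTGGGTGTAGTCTGTGTGGCGGGGTGGCTCATCTGGGG
TTCATCAAAGGATCGCTTCAAGGACCATGAATGATAAAAAAGAACCGCGCGGTAGTCTCATACCCAAACTGTTAACGGTC
TTGTGCTCAGCAATCGGGTCGGACGAATTAGAGGCGTCAGCTATTATTGCCACTGATCCAAGACCCAGGCATCCGAACTC
GAAGAATTGGATGCCGCACGGAAAAACGGTCGTGATCGGCAATTTTGTGGTAAGTTGACGCGGCGGCAGGCCATTAGACA
AAGTATACTCATTGTCCACGGGCATTACAAGCAGTTACGGTGGGCTGAGAGTTTCGTTCTCAGTGACGCAGTATTGCCAT
CGTTAAATTTCCTTAAGCCCCCGTTCTTTCGGCTTAATACGGCTCGTAGATTTCAGTAGTCCTATTCAATATGTGTTAAC
TATTTCCCACTGTTCCCGTTGGTATTATTTGTATGAGTCCTATCGATGAGTTCAAGCCTCGACGACTCGTTTTAAGAACT
GGGTGAAACGTAACCAGTCGCATGCATTAATCATGGGCGATGGCTTGAACAAGTCTCTTATGATCCTCGGTGC
>fly_03
TCACTTTCCTTTCAGCTCAGCCCAGTCCGGAATTGGAGAAGGTGCGCTTAACACTCCAATTTACTCATTTCGATTATGAG
AGGTGCTAAAGGTGCATTGGGTAATCTGACACGCCCGGTAAAGTGGGTGTAGTCTGTGTGGCGGGGTGGCTCATCTGGGG
TTCATCAAAGGATCGCTTCAAGGACCATGAATGATAAAAAAGAACCGCGCGGTAGTCTCATACCCAAACTGTTAACGGTC
TTGTGCTCAGCAATCGGGTCGGACGAATTAGAGGCGTCAGCTATTATTGCCACTGATCCAAGACCCAGGCATCCGAACTC
GAAGAATTGGATGCCGCACGGAAAAACGGTCGTGATCGGCAATYTTGTGGTAAGTTGACGCGGCGGCAGGCCATTAGACA
AAGTATACTCATTGTCCACGGGCATTACAAGCAGTTACGGTGGGCTGAGAGTTTCGTTCTCAGTGACGCAGTATTGCCAT
CGTTAAATTTCCTTAAGCCCCCGTTCTTTCGGCTTAATACGGCTCGTAGATTTCAGTAGTCCTATTCAATATGTGTTAAC
TATTTCCCACTGTTCCCGTTGGTATTATTTGTATGAGTCCTATCGATGAGTTCAAGCCTCGACGACTCGTTTTAAGAACT
GGGTGAAACGTAACCAGTCGCATGCATTAATCATGGGCGATGGCTTGAACAAGTCTCTTATGATCCTCGGTGC
>fly_04
TCACTTTCCTTTCAGCTCAGCCCAGTCCGGAATTGGAGAAGGTGCGCTTAACACTCCAATTTACTCATTTCGATTATGAG
AGGTGCTAAAGGTGCATTGGGTAATCTGAYACGCCCGGTAAAGTGGGTGTAGTCTGTGTGGCGGGGTGGCTCATCTGGGG
TTCATCAAAGGATCGCTTCAAGGACCATGAATGATAAAAAAGAACCGCGCGGTAGTCTCATACCCAAACTGTTAACGGTC
TTGTGCTCAGCAATCGGGTCGGACGAATTAGAGGCGTCAGCTATTATTGCCACTGATCCAAGACCCAGGCATCCGAACTC
GAAGAATTGGATGCCGCACGGAAAAACGGTCGTGATCGGCAATTTTGTGGTAAGTTGACGCGGCGGCAGGCCATTAGACA
AAGTATACTCATTGTCCACGGGCATTACAAGCAGTTACGGTGGGCTGAGAGTTTCGTTCTCAGTGACGCAGTATTGCCAT
CGTTAAATTTCCTTAAGCCCCCGTTCTTTCGGCTTAATACGGCTCGTAGATTTCAGTAGTCCTATTCAATATGTGTTAAC
TATTTCCCACTGTTCCCGTTGGTATTATTTGTATGAGTCCTATCGATGAGTTCAAGCCTCGACGACTCGTTTTAAGAACT
GGGTGAAACGTAACCAGTCGCATGCATTAATCATGGGCGATGGCTTGAACAAGTCTCTTATGATCCTCGGTGC
>fly_05
TCACTTTCCTTTCAGCTCAGCCCAGTCCGGAATTGGAGAAGGTGCGCTTAACACTCCAATTTACTCATTTCGATTAYGAG
AGGTGCTAAAGGTGCATTGGGTAATCTGACACGCCCGGTAAAGTGGGTGTAGTCTGTGTGGCGGGGTGGCTCATCTGGGG
TTCATCAAAGGATCGCTTCAAGGACCATGAATGATAAAAAAGAACCGCGCGGTAGTCTCATACCCAAACTGTTAACGGTC
TTGTGCTCAGCAATCGGGTCGGACGAATTAGAGGCGTCAGCTATTATTGCCACTGATCCAAGACCCAGGCATCCGAACTC
GAAGAATTGGATGCCGCACGGAAAAACGGTCGTGATCGGCAATCWTGTGGTAAGTTGACGCGGCGGCAGGCCATTAGACA
AAGTATACTCATTGTCCACGGGCATTACAAGCAGTTACGGTGGGCTGAGAGTTTCGTTCTCAGTGACGCAGTATTGCCAT
CGTTAAATTTCCTTAAGCCCCCGTTCTTTCGGCTTAATACGGCTCGTAGATTTCAGTAGTCCTATTCAATATGTGTTAAC
TATTTCCCACTGTTCCCGTTGGTATTATTTGTATGAGTCCTATCGATGAGTTCAAGCCTCGACGACTCGTTTTAAGAACT
GGGTGAAACGTAACCAGTCGCATGCATTAATCATGGGCGATGGCTTGAACAAGTCTCTTATGATCCTCGGTGC
>fly_06
TCACTTTCCTTTCAGCTCAGCCCAGTCCGGAATTGGAGAAGGTGCGCTTAACACTCCAATTTACTCATTTCGATTACGAG
AGGTGCTAAAGGTGCATTGGGTAATCTGATACGCCCGGTAAAGTGGGTGTAGTCTGTGTGGCGGGGTGGCTCATCTGGGG
TTCATCAAAGGATCGCTTCAAGGACCATGAATGATAAAAAAGAACCGCGCGGTAGTCTCATACCCAAACTGTTAACGGTC
TTGTGCTCAGCAATCGGGTCGGACGAATTAGAGGCGTCAGCTATTATTGCCACTGATCCAAGACCCAGGCATCCGAACTC
GAAGAATTGGATGCCGCACGGAAAAACGGTCGTGATCGGCAATCTTGTGGTAAGTTGACGCGGCGGCAGGCCATTAGACA
AAGTATACTCATTGTCCACGGGCATTACAAGCAGTTACGGTGGGCTGAGAGTTTCGTTCTCAGTGACGCAGTATTGCCAT
CGTTAAATTTCCTTAAGCCCCCGTTCTTTCGGCTTAATACGGCTCGTAGATTTCAGTAGTCCTATTCAATATGTGTTAAC
TATTTCCCACTGTTCCCGTTGGTATTATTTGTATGAGTCCTATCGATGAGTTCAAGCCTCGACGACTCGTTTTAAGAACT
GGGTGAAACGTAACCAGTCGCATGCATTAATCATGGGCGATGGCTTGAACAAGTCTCTTATGATCCTCGGTGC
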