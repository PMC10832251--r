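gene_name: Vssc
reference_labels:
- NW_026712250.1 position 125581 (L1014F)
- NM_001286885.1 (para-like mRNA)
reference_fasta: vssc_synthetic_reference.fasta
intron:
  after_position: 131
  length: 1700
sites:
- name: M918T
  codon_number: 918
  wild_aa: M
  mutant_aa: T
  wild_codon: ATG
  mutant_codon: ACG
  guide_sequence: AATTTACTCATTTCGATTAC
  codon_offset: -2
  variable_position: 2
- name: T929I
  codon_number: 929
  wild_aa: T
  mutant_aa: I
  wild_codon: ACA
  mutant_codon: ATA
  guide_sequence: GGTGCATTGGGTAATCTGAT
  codon_offset: -2
  variable_position: 2
- name: L1014F
  codon_number: 1014
  wild_aa: L
  mutant_aa: F
  wild_codon: CTT
  mutant_codon: TTT
  guide_sequence: ACGGTCGTGATCGGCAATT
  codon_offset: -1
  variable_position: 1
- name: L1014H
  codon_number: 1014
  wild_aa: L
  mutant_aa: H
  wild_codon: CTT
  mutant_codon: CAT
  guide_sequence: CGGTCGTGATCGGCAATCA
  codon_offset: -2
  variable_position: 2
assay:
  primers:
  - name: kdr1
    sequence: AAGGATCGCTTCAAGG
    declared_direction: forward
    annealing_temp: 54.0
  - name: kdr2
    sequence: GTCGTGATCGGCAATT
    declared_direction: reverse
    annealing_temp: 54.0
  - name: kdr3
    sequence: CGTCAACTTACCACAAG
    declared_direction: forward
    annealing_temp: 54.0
  - name: kdr4
    sequence: TTCACCCAGTTCTTAAAACGAG
    declared_direction: reverse
    annealing_temp: 54.0
  pairs:
    control:
    - kdr1
    - kdr4
    susceptible:
    - kdr1
    - kdr3
    resistant:
    - kdr2
    - kdr4
  expected_sizes:
    control: 480
    susceptible: 200
    resistant: 280
  size_tolerance: 0.1
sequencing_primers:
- name: K1
  sequence: TCGCTTCAAGGACCATGAAT
  declared_direction: forward
- name: K2
  sequence: TTACGTTTCACCCAGTTCTTA
  declared_direction: reverse
- name: 4Mut_kdr_F
  sequence: TCCGGAATTGGAGAAGGTGC
  declared_direction: forward
- name: 4Mut_kdr_R
  sequence: TCAAGCCATCGCCCATGATT
  declared_direction: reverse
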