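# kdrscreen

Screening house fly (*Musca domestica*) populations for knockdown
resistance (*kdr*) to pyrethroid insecticides — for medical-entomology and
vector-control labs that genotype target-site mutations in the
voltage-sensitive sodium channel (VSSC) and run CDC bottle bioassays.

Repeated pyrethroid use selects amino acid substitutions in the VSSC that
make the channel insensitive to the insecticide. The package covers the
four mutations relevant to house flies — L1014F (*kdr*), L1014H
(*kdr-his*), M918T (*super-kdr*) and T929I — and the three ways they are
screened in practice:

1. **Sequence-based genotyping.** Each mutation is located in a Sanger
   consensus sequence (gDNA or cDNA, either strand) by a short guide
   (anchor) oligomer, and the marked codon is read with IUPAC ambiguity
   codes: at L1014F, `CTT` calls SS (*sus/sus*), `TTT` calls RR
   (*kdr/kdr*), and `YTT` — Y being the C/T double peak of a heterozygous
   chromatogram — calls RS.
2. **PASA (PCR Amplification of Specific Alleles).** Three reactions per
   insect (control, susceptible-specific, resistant-specific primer pairs
   kdr1+kdr4, kdr1+kdr3, kdr2+kdr4) whose gel bands (nominal 480/200/280
   bp) encode the genotype. The in-silico simulator models primer binding
   with 3'-terminal allele discrimination on diploid templates and
   interprets band patterns back into genotypes.
3. **CDC bottle bioassay.** Cumulative mortality at 15-min intervals
   (0–120 min) in insecticide-coated bottles. A susceptible-strain dose
   ladder fixes the diagnostic dose and time (the smallest dose killing
   100% of susceptible flies, and the earliest time it does so); field
   populations with Abbott-corrected mortality below 100% at that point
   are classified resistant.

Population screening uses the standard allele accounting
(`kdr_count = 2·n_RR + n_RS`, frequency `kdr_count / 2N`) and a
Hardy–Weinberg equilibrium test: with estimated allele frequency *p*,
expected genotype counts are *Np²*, *2Npq*, *Nq²* and

> χ² = Σ (obs − exp)² / exp,  df = 1 (no continuity correction),

monomorphic samples being flagged and excluded from deviation counts.

A seeded synthetic-data generator (HWE populations with an optional
inbreeding-style deviation coefficient, IUPAC-coded consensus sequences
with a ~1700-bp intron in the gDNA form, logistic-in-time mortality
curves) makes every stage testable offline; the packaged reference
sequence is synthetic and labelled as such.

## Worked example

The package ships a complete worked example: the 2023 Abu Dhabi survey
(19 locations, 279 flies genotyped at L1014F by PASA) and a 16-location
deltamethrin bottle-bioassay screen.

```r
library(kdrscreen)

counts <- abudhabi_survey_counts()
hwe_test(counts[counts$location == "Mina Zayed", ])
#> <hwe_result> chi2 = 0.9742, df = 1, p = 0.3236

summarize_populations(counts)
#> <population_summary> 19 location(s), 279 insects
#>   genotypes: RR 14 (5.0%), RS 102 (36.6%), SS 163 (58.4%)
#>   locations with kdr allele: 18/19; with RR: 10/19 (52.6%)
#>   deviating from HWE at alpha = 0.05: 3
```

So 5.0% of flies are homozygous resistant, 36.6% heterozygous, the kdr
allele occurs at 18 of 19 locations, RR insects at 10 of 19 (52.6%), and
three locations (Hadbat Al Zafranah, Al Danah, Al Shuwaymah) deviate from
Hardy–Weinberg equilibrium at α = 0.05.

```r
calls <- classify_mortality_table(kdr_example("abudhabi2023_bioassay.csv"),
                                  dose = 4.5, time = 60)
subset(calls, status == "resistant")[, c(1, 4, 6)]
#>     location    status time_to_full_mortality
#> 11 Al Shwaib resistant                     90
#> 16  Al Aflaj resistant                     90
prevalence(calls)
#> [1] 12.5
```

Two of 16 locations (12.5%) survive the (4.5 µg/ml, 60 min) diagnostic,
reaching full mortality only at 90 min.

Sequence genotyping, on the demonstration FASTA (note the heterozygous
T929I codon `AYA`, and that an L1014F-homozygous codon `TTT` leaves the
L1014H test INDETERMINATE — the wild context needed to score it is gone):

```r
df <- genotype_fasta(kdr_example("demo_flies_cdna.fasta"))
subset(df, sequence_id == "fly_04")[, c("site", "codon", "genotype", "amino_acids")]
#>      site codon      genotype amino_acids
#> 13  M918T   ATG            SS           M
#> 14  T929I   AYA            RS         I/T
#> 15 L1014F   TTT            RR           F
#> 16 L1014H   TTT INDETERMINATE           F
```

A command-line wrapper with subcommands `genotype`, `pasa`, `popgen`,
`bioassay` and `simulate` is installed at
`system.file("scripts", "kdrscreen", package = "kdrscreen")`.

## Vignette

`vignettes/kdr-screening-methods.Rmd` documents the models and the design
choices: the guide-anchor geometry (why the published guides carry the
mutant base at their 3' tip), the PASA amplicon geometry and its relation
to the nominal band sizes, the fixed-32 allele denominator of the survey
table, the HWE test conventions, the Abbott correction and validity rules,
and what the synthetic data do and do not emulate.
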