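---
title: "Methods: kdr screening in house flies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kdr screening in house flies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdrscreen)
```

## Scope and model

Knockdown resistance (*kdr*) in the house fly is caused by amino acid
substitutions in the voltage-sensitive sodium channel (VSSC), the target
of pyrethroids and DDT. This package implements the desk side of a field
screening campaign: genotype individual flies at four VSSC mutations
(M918T, T929I, L1014F, L1014H), summarise per-location genotype counts
into allele frequencies and Hardy–Weinberg (HWE) tests, and classify CDC
bottle-bioassay mortality series against a diagnostic dose and time. A
synthetic-data generator supplies the sequences, populations and
mortality curves needed to validate every stage without external data.

## Guide-anchor genotyping

Each mutation site is defined by a short unambiguous guide oligomer, the
wild and mutant codons, and the variable codon position. Genotyping a
consensus sequence proceeds in two steps.

**Anchoring.** The guide is slid over the query and its reverse
complement, counting mismatches; an IUPAC code in the query matches any
of its expansions. Guide positions overlapping the marked codon are
*excluded* from the mismatch count, because those bases depend on the
genotype being read. The packaged guides all end *on* the codon they
mark, carrying the mutant base at their 3' tip (L1014F:
`...GGCAAT`+`T`, the mutant first codon base; L1014H: `...GGCAAT`+`CA`,
wild C then mutant A; analogously for M918T and T929I). This is why the
codon offsets are negative (−1 for L1014F, −2 for the others) and why
codon masking is necessary: the two 1014 guides could not both sit
strictly 5′ of the same codon, since they end in incompatible bases. The
default mismatch budget is 1 across the guide; ties at the best count
raise an explicit ambiguity error rather than picking a locus silently —
for 17–20-mers a wrong-locus call is worse than a failed one.

**Codon rule.** With the codon extracted at the guide-relative offset:
the wild base at the variable position calls SS, the mutant base RR, and
the IUPAC code whose expansion is *exactly* {wild, mutant} calls RS
(`Y` at L1014F, the C/T double peak of a heterozygous chromatogram).
Anything else — a third base, a triple ambiguity such as `H`, a
truncated codon, a missing anchor — is INDETERMINATE, which is a value,
not an error. At the non-variable positions the wild base must be
*among* the expansions of the observed base. The tolerant containment
rule (rather than exact equality) is deliberate: an apparent
L1014F/L1014H compound heterozygote (`Y` at position 1, `W` at position
2) is then reported as RS at both sites, each carrying its own evidence,
with no attempt at joint haplotype resolution. Conversely an
L1014F-homozygous `TTT` codon leaves the L1014H test INDETERMINATE: the
wild context needed to score H is absent. Raw chromatogram (AB1) peak
processing is out of scope; the portable interface is the base-called
consensus with IUPAC codes.

Input form is inferred from anchor geometry: when the 918/929-region and
1014-region anchors are at least one intron length (default 1700 bp)
apart the sequence is reported as gDNA, when both are present closer
together as cDNA, otherwise unknown. Internally coordinates are 0-based
half-open; CSV output is 1-based.

## PASA in-silico

PASA genotypes L1014F on a gel: three reactions (control kdr1+kdr4,
susceptible-specific kdr1+kdr3, resistant-specific kdr2+kdr4) with
nominal band sizes 480, 200 and 280 bp. Primer binding is modelled
purely combinatorially: a site is valid when the primer's 3'-terminal
base matches the template exactly (`three_prime_exact = 1`) and no other
base mismatches (`max_internal_mismatches = 0`). Thermodynamics is not
modelled; the 3'-terminal rule is the textbook PASA discrimination
mechanism and suffices to reproduce the genotype logic. As published,
kdr2 is labelled "Reverse" and kdr3 "Forward", yet the reaction pairing
requires each pair to face each other; the simulator therefore searches
both orientations and uses whichever yields a facing pair, trusting
geometry over labels.

The packaged synthetic reference deserves a precise statement. The three
nominal sizes satisfy 200 + 280 = 480, which forces the two inner-primer
footprints to be *disjoint* intervals inside the control amplicon — and
a single SNP cannot lie inside both. No template therefore exists on
which both allele-specific primers discriminate at codon 1014 *and* the
products measure exactly 200 and 280 bp: with both inner primers
3'-anchored on the variable base (kdr2 ending on the mutant `T` on the
coding strand, kdr3 ending on the wild `C` from the opposite strand),
the two inner products must sum to 480 + 16 + 17 − 1 = 512 bp. The
packaged reference keeps the mechanism exact and the control at exactly
480 bp, yielding inner products of 213 and 299 bp; these fall within the
±10% gel-sizing tolerance of the nominal 200/280, so band
interpretation, and the genotype → bands → genotype loop, are exact. The
published sizes are treated as what they are on a 1.5% agarose gel:
nominal. Gel interpretation: bands match the nearest expected size
within `size_tolerance` (default 0.10); unmatched bands are ignored with
a warning; without a control band the assay failed and the call is
INDETERMINATE regardless of other bands, as is a control band with
neither allele-specific product.

## Population statistics

Allele accounting is the usual diploid count: `kdr = 2·n_RR + n_RS`,
frequency `kdr / 2N`. The packaged survey's "% RR alleles" column,
however, divides by a *fixed* 32 allele copies (a nominal 16 flies per
site) for every location regardless of its actual N — reproducible via
`kdr_allele_percent(counts)` (default denominator 32), while summaries
default to the statistically sound 2N. The fixed-32 convention is
reproduced, not endorsed. One printed row (Hili) is internally
inconsistent: its counts (1 RR, 4 RS of 20) give 6/32 = 18.8 under the
fixed-32 convention, while the printed column shows 15.6; the fixture
transcribes the printed value verbatim and the reproduction test
documents the discrepancy rather than silently correcting either side.

The HWE test is the Pearson chi-square over the three genotype classes
against expectations *Np²*, *2Npq*, *Nq²* with *p* estimated from the
sample, referred to 1 degree of freedom (3 classes − 1 − 1 estimated
parameter), with **no** Yates continuity correction — exactly the
convention that reproduces the survey's printed statistics from its
printed counts (with correction they do not match). Monomorphic samples
report χ² = 0 with an undefined p-value and are excluded from
deviation-count denominators. No multiple-testing correction is applied
across locations by default (the survey applies none); a Bonferroni flag
exists. The chi-square approximation at 1 df is used as-is; an exact
(Fisher-type) HWE test is out of scope. Its adequacy at survey-like
sizes is checked empirically: under the null (p = 0.3, N = 100, 2000
seeded replicates) the suite requires the type-I error rate at α = 0.05
to lie in [0.03, 0.08].

## Bottle bioassay

Mortality series are cumulative dead counts on a strictly increasing
grid (default 0–120 min by 15). Classification pools the treated
bottles (sum of dead over sum exposed) rather than averaging per bottle,
matching aggregate-mortality practice in CDC-style assays. Control
mortality is handled by Abbott's correction, (T − C)/(1 − C), clamped to
[0, 1]; runs whose control mortality exceeds 10% at the diagnostic time
are invalid. The susceptibility threshold defaults to 100% corrected
mortality at the diagnostic time — the rule a diagnostic dose implies —
with the CDC's laxer 90/97% bands available via `threshold`. The
diagnostic itself is determined on a susceptible-strain ladder as the
smallest dose with complete kill in *every* bottle within the window,
and the earliest grid time achieving it. Dose–response (LC50) and
knockdown-time regressions are out of scope.

## Synthetic data

The generator emulates, deterministically under a seed:

* diploid genotypes with `P(RR) = p² + Fpq`, `P(RS) = 2pq(1−F)`,
  `P(SS) = q² + Fpq` — `F` is an inbreeding-style deviation dial for
  *testing* HWE machinery, not an inference model;
* consensus sequences: the synthetic reference with per-site codons
  substituted, heterozygotes as IUPAC codes; the gDNA form inserts a
  fixed pseudo-random 1700-bp intron between the 918/929 and 1014
  regions, upstream of the PASA region (as in the real gene, where the
  PASA amplicon is intron-free but one gDNA amplicon cannot span both
  the 918/929 and 1014 mutations — the motivation for cDNA-based
  four-mutation sequencing);
* bioassay curves: logistic-in-time cumulative kill probability clamped
  to 1 at a per-status full-kill time (susceptible 60 min, resistant 90
  min, mirroring the packaged screen), with optional binomial sampling
  of incremental deaths from survivors, which keeps series monotone by
  construction.

It does **not** emulate sequencing error, chimeras, chromatogram peak
shapes, primer thermodynamics, or multi-generation selection — so
passing tests demonstrate the pipeline's logic, not robustness to noisy
field data. The synthetic reference is non-biological: guides and primer
footprints are placed at the geometry described above inside seeded
random spacers (seed 20230901, with an automatic collision check against
accidental guide/primer matches), and codon spacing is frame-consistent
with the house fly *para* numbering used in the mutation names. The
packaged bioassay fixture encodes each location's published status and
time-to-100% as deterministic curves; the original per-bottle layout was
not published, so the fixture represents the outcome, not the raw data.

## Numerical conventions and problem sizes

Display rounding is half-up to one decimal (46.875 → 46.9; half-to-even
would print 46.8), matching the survey's style; CSV outputs keep full
precision. Codon translation uses the standard genetic code; `U` is
accepted and mapped to `T`; matching is case-insensitive. The validation
suite runs at desk scale — populations of 16–10 000, 2000-replicate null
calibration, 200-replicate bioassay recovery — chosen so the whole suite
completes in well under a minute per module while keeping Monte-Carlo
standard errors far below the tolerances tested.

## Known limitations

* Calls at codon 1014 treat L1014F and L1014H as separate tests;
  compound heterozygotes are flagged, not phased.
* The PASA simulator's product sizes on the packaged reference are
  nominal-equivalent (213/299 vs 200/280), as derived above; assays with
  different primer footprints need their own assay definition.
* The HWE test is asymptotic; for very small N or rare alleles an exact
  test would be preferable.
* Bioassay classification reproduces a per-location status from pooled
  bottles; bottle-level variance is not modelled in the classifier.
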