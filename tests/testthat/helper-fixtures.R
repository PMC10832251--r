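# Shared objects for the suite: the packaged model/assay/reference and a
# couple of brute-force oracles kept deliberately independent of the
# implementation code paths they check.

test_model <- default_gene_model()
test_assay <- default_assay()
test_reference <- build_vssc_reference()

# Enumerate the IUPAC expansions of a codon and classify by exact set
# comparison against {wild, mutant}. Valid over unambiguous codons and
# single-ambiguity codons at the variable position.
oracle_classify_codon <- function(codon, site) {
  chars <- strsplit(codon, "")[[1]]
  sets <- lapply(chars, function(b) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[b]], "")[[1]]
  })
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  expansions <- sort(unique(apply(grid, 1, paste, collapse = "")))
  if (identical(expansions, site$wild_codon)) return("SS")
  if (identical(expansions, site$mutant_codon)) return("RR")
  if (identical(expansions, sort(c(site$wild_codon, site$mutant_codon)))) {
    return("RS")
  }
  "INDETERMINATE"
}

# Naive sliding-window Hamming scan (no ambiguity handling, no masking):
# used on unambiguous queries with guides that do not overlap their codon.
oracle_hamming_positions <- function(query, pattern, max_mm) {
  q <- strsplit(query, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  hits <- integer()
  for (s in seq_len(length(q) - length(p) + 1)) {
    if (sum(q[s:(s + length(p) - 1)] != p) <= max_mm) hits <- c(hits, s)
  }
  hits
}

# Substitute the 3-base codon of `site` in the packaged reference.
reference_with_codon <- function(codon, site, reference = test_reference) {
  s <- reference$cdna
  start <- reference$codon_starts[[site$name]]
  paste0(substr(s, 1, start - 1), codon, substr(s, start + 3, nchar(s)))
}

genotype_vector <- function(report) {
  vapply(report$calls, `[[`, character(1), "genotype")
}

rc_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
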