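# Anchor location and SS/RS/RR calling from consensus sequences.

test_that("locate_anchor finds guides on either strand and counts mismatches", {
  ref <- test_model$reference_sequence
  site <- test_model$sites$L1014F

  fwd <- locate_anchor(ref, site, max_mismatches = 0)
  expect_equal(fwd$strand, "forward")
  expect_equal(fwd$mismatches, 0L)
  # guide ends on the codon's first base
  expect_equal(fwd$position + nchar(site$guide_sequence) + site$codon_offset,
               test_reference$codon_starts[["L1014F"]] - 1L)

  rc <- locate_anchor(rc_str(ref), site, max_mismatches = 0)
  expect_equal(rc$strand, "reverse-complement")
  # coordinates are reported on the forward query
  expect_equal(rc$position, nchar(ref) - (fwd$position +
                                            nchar(site$guide_sequence)))
})

test_that("one substitution inside the guide needs max_mismatches 1", {
  ref <- test_model$reference_sequence
  site <- test_model$sites$M918T
  a0 <- locate_anchor(ref, site, max_mismatches = 0)
  # mutate a guide base that is not part of the codon (guide position 5)
  pos <- a0$position + 5L
  stopifnot(substr(ref, pos, pos) == substr(site$guide_sequence, 5, 5))
  mutated <- ref
  substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                       substr(ref, pos, pos))[1]
  a1 <- locate_anchor(mutated, site, max_mismatches = 1)
  expect_equal(a1$mismatches, 1L)
  expect_equal(a1$position, a0$position)
  expect_null(locate_anchor(mutated, site, max_mismatches = 0))
})

test_that("locate_anchor agrees with a naive Hamming scan on planted guides", {
  # guide placed in a random background at a known position, with 0 or 1
  # substitutions; the site codon sits beyond the guide (offset 0) so the
  # oracle needs no masking
  site <- mutation_site("X1", 10, "L", "F", "CTT", "TTT",
                        "GGATCCTTAGCAGCAT", 0, 1)
  set.seed(42)
  for (rep in 1:20) {
    bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
    at <- sample(50:250, 1)
    q <- paste0(substr(bg, 1, at - 1), site$guide_sequence,
                substr(bg, at, 300))
    n_sub <- sample(0:1, 1)
    if (n_sub == 1) {
      i <- at + sample(0:15, 1)
      substr(q, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, i, i))[1]
    }
    oracle_hits <- oracle_hamming_positions(q, site$guide_sequence, 1)
    got <- tryCatch(locate_anchor(q, site, max_mismatches = 1,
                                  search_both_strands = FALSE),
                    error = function(e) "ambiguous")
    if (identical(got, "ambiguous")) {
      expect_gt(length(oracle_hits), 1)
    } else {
      best <- oracle_hits[which.min(vapply(oracle_hits, function(s) {
        sum(strsplit(substr(q, s, s + 15), "")[[1]] !=
              strsplit(site$guide_sequence, "")[[1]])
      }, numeric(1)))]
      expect_equal(got$position + 1L, best)
    }
  }
})

test_that("tied anchor matches raise an ambiguity error listing positions", {
  site <- mutation_site("X1", 10, "L", "F", "CTT", "TTT",
                        "GGATCCTTAGCAGCAT", 0, 1)
  q <- paste0("AAAACCCC", site$guide_sequence, "TTTTGGGG",
              site$guide_sequence, "CTTAAA")
  expect_error(locate_anchor(q, site), "ambiguous anchor")
})

test_that("call_site applies the codon genotype rule", {
  f <- test_model$sites$L1014F
  h <- test_model$sites$L1014H
  expect_equal(call_site(reference_with_codon("CTT", f), f)$genotype, "SS")
  expect_equal(call_site(reference_with_codon("YTT", f), f)$genotype, "RS")
  expect_equal(call_site(reference_with_codon("TTT", f), f)$genotype, "RR")
  # W = A/T expands to exactly {mutant, wild} at L1014H position 2
  expect_equal(call_site(reference_with_codon("CWT", h), h)$genotype, "RS")
  # triple ambiguity at the variable position is not an RS call
  expect_equal(call_site(reference_with_codon("HTT", f), f)$genotype,
               "INDETERMINATE")
  # anchor absent entirely
  expect_equal(call_site(paste(rep("ACGT", 50), collapse = ""), f)$genotype,
               "INDETERMINATE")
  # heterozygous call carries both amino acids
  expect_setequal(call_site(reference_with_codon("YTT", f), f)$amino_acids,
                  c("L", "F"))
})

test_that("call_site matches the expansion-set oracle across the codon space", {
  singles <- c("A", "C", "G", "T")
  doubles <- c("M", "R", "W", "S", "Y", "K")
  all_unambig <- names(Biostrings::GENETIC_CODE)
  for (site in test_model$sites) {
    vp <- site$variable_position
    wild <- strsplit(site$wild_codon, "")[[1]]
    ambig_codons <- vapply(doubles, function(code) {
      chars <- wild; chars[vp] <- code; paste(chars, collapse = "")
    }, character(1))
    for (codon in c(all_unambig, ambig_codons)) {
      got <- call_site(reference_with_codon(codon, site), site)$genotype
      expect_equal(got, oracle_classify_codon(codon, site),
                   label = paste(site$name, codon))
    }
  }
})

test_that("calls are invariant to strand and to the gDNA intron", {
  combos <- list(
    c(M918T = "SS", T929I = "SS", L1014F = "SS", L1014H = "SS"),
    c(M918T = "RS", T929I = "RR", L1014F = "SS", L1014H = "SS"),
    c(M918T = "SS", T929I = "RS", L1014F = "RR", L1014H = "SS"),
    c(M918T = "RR", T929I = "SS", L1014F = "RS", L1014H = "SS"),
    c(M918T = "SS", T929I = "SS", L1014F = "SS", L1014H = "RS"))
  for (g in combos) {
    truth <- data.frame(id = "x", as.list(g), stringsAsFactors = FALSE)
    cdna <- render_sequences(truth, "cDNA", reference = test_reference)[[1]]
    gdna <- render_sequences(truth, "gDNA", reference = test_reference)[[1]]
    r_c <- call_all_sites(cdna, test_model)
    r_g <- call_all_sites(gdna, test_model)
    r_rc <- call_all_sites(rc_str(cdna), test_model)
    expect_equal(genotype_vector(r_c), genotype_vector(r_g))
    expect_equal(genotype_vector(r_c), genotype_vector(r_rc))
    expect_equal(r_c$input_kind, "cDNA")
    expect_equal(r_g$input_kind, "gDNA")
  }
})

test_that("genotype_fasta recovers the demonstration truth table", {
  df <- genotype_fasta(kdr_example("demo_flies_cdna.fasta"), test_model)
  truth <- read.csv(kdr_example("demo_flies_truth.csv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(df), 6 * 4)
  for (i in seq_len(nrow(truth))) {
    for (s in names(test_model$sites)) {
      got <- df$genotype[df$sequence_id == truth$id[i] & df$site == s]
      expect_equal(got, truth[[paste0("call_", s)]][i],
                   label = paste(truth$id[i], s))
    }
  }
  expect_true(all(df$input_kind == "cDNA"))
})

test_that("genotype_fasta handles degenerate inputs", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(genotype_fasta(empty, test_model), "no records|parse")
  expect_error(genotype_fasta("no/such/file.fasta", test_model),
               "cannot read")
  # a record without the VSSC region: every call INDETERMINATE
  unrelated <- withr::local_tempfile(fileext = ".fasta")
  set.seed(7)
  writeLines(c(">random", paste(sample(c("A", "C", "G", "T"), 400,
                                       replace = TRUE), collapse = "")),
             unrelated)
  df <- genotype_fasta(unrelated, test_model)
  expect_true(all(df$genotype == "INDETERMINATE"))
  expect_equal(unique(df$input_kind), "unknown")
  # duplicate ids get suffixed with a warning
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">fly", test_model$reference_sequence,
               ">fly", test_model$reference_sequence), dup)
  expect_warning(df2 <- genotype_fasta(dup, test_model), "duplicate")
  expect_equal(length(unique(df2$sequence_id)), 2)
})

test_that("an apparent L1014F/L1014H compound heterozygote reports both sites RS", {
  s <- test_reference$cdna
  start <- test_reference$codon_starts[["L1014F"]]
  substr(s, start, start) <- "Y"
  substr(s, start + 1, start + 1) <- "W"
  expect_warning(rep <- call_all_sites(s, test_model),
                 "compound heterozygote")
  g <- genotype_vector(rep)
  expect_equal(unname(g[c("L1014F", "L1014H")]), c("RS", "RS"))
})
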