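# Synthetic-data generation: a seeded synthetic VSSC reference with the
# guide/primer geometry needed by the genotype caller and the PASA
# simulator, diploid genotype populations under (or deviating from) HWE,
# rendered gDNA/cDNA consensus sequences with IUPAC heterozygotes, and
# bottle-bioassay mortality curves.

# Run code under a temporary RNG state so generators are reproducible
# without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

INTRON_SEED <- 104729L
DEFAULT_INTRON_LENGTH <- 1700L
REFERENCE_SEED <- 20230901L

#' Deterministic synthetic intron sequence
#'
#' The gDNA rendering inserts this fixed pseudo-random intron between the
#' 918/929 region and the 1014 region. Generated from an internal fixed
#' seed so gDNA renderings are reproducible everywhere.
#'
#' @param length Intron length in bp (default 1700, the approximate length
#'   of the large VSSC intron separating the super-kdr region from codon
#'   1014).
#' @return A nucleotide string.
#' @export
intron_sequence <- function(length = DEFAULT_INTRON_LENGTH) {
  with_seed(INTRON_SEED, random_bases(length))
}

# Published primer/guide building blocks (5'-3' on the coding strand, or
# as spanning the coding strand for the reverse elements).
REF_PARTS <- list(
  fourmut_f   = "TCCGGAATTGGAGAAGGTGC",
  g918_prefix = "AATTTACTCATTTCGATT",   # guide minus its codon-overlap tip
  codon918    = "ATG",
  g929_prefix = "GGTGCATTGGGTAATCTG",
  codon929    = "ACA",
  kdr1        = "AAGGATCGCTTCAAGG",
  k1_tail     = "ACCATGAAT",            # completes the K1 footprint
  g1014_prefix = "ACGGTCGTGATCGGCAAT",
  codon1014   = "CTT",
  kdr3_tail   = "GTGGTAAGTTGACG",       # with codon pos 1, revcomp(kdr3)
  rc_kdr4     = "CTCGTTTTAAGAACTGGGTGAA",
  k2_tail     = "ACGTAA"                # completes the revcomp(K2) footprint
)

#' Build the packaged synthetic VSSC reference
#'
#' Constructs a non-biological coding-strand (cDNA) sequence in which all
#' four guide anchors occur uniquely and the PASA primers have the exact
#' geometry used by the band simulator: both allele-specific primers are
#' 3'-anchored on the variable base of codon 1014, the control amplicon
#' (kdr1 + kdr4) measures exactly 480 bp, and the susceptible- and
#' resistant-specific amplicons measure 213 and 299 bp (within the 10% gel
#' tolerance of the nominal 200/280 bp). Spacer sequences are seeded
#' pseudo-random and validated against accidental guide or primer matches;
#' the gDNA form carries a 1700-bp intron between the 918/929 region and
#' the 1014 region.
#'
#' @param seed Integer seed for the spacer sequences.
#' @param intron_length gDNA intron length in bp.
#' @return A list: `cdna`, `gdna`, `intron`, `intron_after` (1-based cDNA
#'   position the intron follows), `codon_starts` (named, 1-based cDNA
#'   coordinates of the four mutation codons).
#' @export
build_vssc_reference <- function(seed = REFERENCE_SEED,
                                 intron_length = DEFAULT_INTRON_LENGTH) {
  p <- REF_PARTS
  for (try in 0:49) {
    spacers <- with_seed(seed + try, list(
      pad5 = random_bases(25L), a = random_bases(12L),
      s918 = random_bases(12L), b = random_bases(56L),
      c = random_bases(153L), d = random_bases(245L),
      e = random_bases(15L),
      rc_4mut_r = "AATCATGGGCGATGGCTTGA",
      pad3 = random_bases(25L)))
    cdna <- paste0(spacers$pad5, p$fourmut_f, spacers$a,
                   p$g918_prefix, p$codon918, spacers$s918,
                   p$g929_prefix, p$codon929, spacers$b,
                   p$kdr1, p$k1_tail, spacers$c,
                   p$g1014_prefix, p$codon1014, p$kdr3_tail, spacers$d,
                   p$rc_kdr4, p$k2_tail, spacers$e,
                   spacers$rc_4mut_r, spacers$pad3)
    intron <- intron_sequence(intron_length)
    intron_after <- 131L  # 20 bp after codon 929, upstream of the kdr1 site
    gdna <- paste0(substr(cdna, 1L, intron_after), intron,
                   substr(cdna, intron_after + 1L, nchar(cdna)))
    if (reference_geometry_ok(cdna, gdna)) {
      codon_starts <- c(M918T = 76L, T929I = 109L, L1014F = 364L,
                        L1014H = 364L)
      return(list(cdna = cdna, gdna = gdna, intron = intron,
                  intron_after = intron_after, codon_starts = codon_starts))
    }
  }
  stop("could not build a collision-free reference; widen the seed search",
       call. = FALSE)  # nocov
}

# The spacer draws must not create second guide anchors or extra primer
# sites; checked on both the cDNA and the gDNA renderings.
reference_geometry_ok <- function(cdna, gdna) {
  sites <- builtin_sites()
  for (seqn in c(cdna, gdna)) {
    for (site in sites) {
      hit <- tryCatch(locate_anchor(seqn, site, max_mismatches = 0L),
                      error = function(e) NULL)
      if (is.null(hit) || hit$strand != "forward") return(FALSE)
    }
    for (pr in builtin_primers()) {
      n_expected <- c(kdr1 = 1L, kdr2 = 0L, kdr3 = 1L, kdr4 = 1L)[[pr$name]]
      if (nrow(find_binding_sites(seqn, pr)) != n_expected) return(FALSE)
    }
  }
  TRUE
}

builtin_sites <- function() {
  list(
    mutation_site("M918T", 918L, "M", "T", "ATG", "ACG",
                  "AATTTACTCATTTCGATTAC", -2L, 2L),
    mutation_site("T929I", 929L, "T", "I", "ACA", "ATA",
                  "GGTGCATTGGGTAATCTGAT", -2L, 2L),
    mutation_site("L1014F", 1014L, "L", "F", "CTT", "TTT",
                  "ACGGTCGTGATCGGCAATT", -1L, 1L),
    mutation_site("L1014H", 1014L, "L", "H", "CTT", "CAT",
                  "CGGTCGTGATCGGCAATCA", -2L, 2L)
  )
}

builtin_primers <- function() {
  list(primer("kdr1", "AAGGATCGCTTCAAGG", "forward", 54),
       primer("kdr2", "GTCGTGATCGGCAATT", "reverse", 54),
       primer("kdr3", "CGTCAACTTACCACAAG", "forward", 54),
       primer("kdr4", "TTCACCCAGTTCTTAAAACGAG", "reverse", 54))
}

#' Simulate diploid genotypes under (or deviating from) HWE
#'
#' Draws `n_individuals` genotypes at one biallelic locus with
#' `P(RR) = p^2 + F p q`, `P(RS) = 2 p q (1 - F)`, `P(SS) = q^2 + F p q`,
#' where `p` is the kdr allele frequency and `F` an inbreeding-style
#' deviation coefficient (`F = 0` samples exact HWE proportions; `F = 1`
#' forces homozygosity; negative `F` gives heterozygote excess). `F` is a
#' testing device for generating HWE-deviating populations, not a fitted
#' quantity.
#'
#' @param n_individuals Number of diploid individuals.
#' @param kdr_allele_frequency `p`, in `[0, 1]`.
#' @param inbreeding_F Deviation coefficient in `[-1, 1]`; the implied
#'   genotype probabilities must all be non-negative.
#' @param seed Optional integer seed (local to this call).
#' @param location Label for the returned count row.
#' @return A list: `counts` (single-row [genotype_counts()]) and `truth`
#'   (data.frame `id`, `genotype`).
#' @export
simulate_genotype_counts <- function(n_individuals, kdr_allele_frequency,
                                     inbreeding_F = 0, seed = NULL,
                                     location = "synthetic") {
  p <- kdr_allele_frequency
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("kdr_allele_frequency must be in [0, 1]", call. = FALSE)
  }
  if (!is_count(n_individuals) || n_individuals < 1) {
    stop("n_individuals must be a positive integer", call. = FALSE)
  }
  q <- 1 - p
  probs <- c(RR = p^2 + inbreeding_F * p * q,
             RS = 2 * p * q * (1 - inbreeding_F),
             SS = q^2 + inbreeding_F * p * q)
  if (any(probs < -1e-12)) {
    stop("inbreeding_F = ", inbreeding_F, " gives negative genotype ",
         "probabilities at p = ", p, call. = FALSE)
  }
  probs <- pmax(probs, 0)
  draw <- function() sample(names(probs), n_individuals, replace = TRUE,
                            prob = probs)
  genotypes <- if (is.null(seed)) draw() else with_seed(seed, draw())
  truth <- data.frame(
    id = sprintf("fly_%0*d", nchar(as.character(n_individuals)),
                 seq_len(n_individuals)),
    genotype = genotypes, stringsAsFactors = FALSE)
  counts <- genotype_counts(location,
                            n_RR = sum(genotypes == "RR"),
                            n_RS = sum(genotypes == "RS"),
                            n_SS = sum(genotypes == "SS"))
  list(counts = counts, truth = truth)
}

substitute_codon <- function(seqn, start, site, genotype) {
  codon <- switch(genotype,
                  SS = site$wild_codon,
                  RR = site$mutant_codon,
                  RS = {
                    vp <- site$variable_position
                    chars <- seq_chars(site$wild_codon)
                    chars[vp] <- ambiguity_code(
                      c(substr(site$wild_codon, vp, vp),
                        substr(site$mutant_codon, vp, vp)))
                    paste(chars, collapse = "")
                  },
                  stop("cannot render genotype '", genotype, "'",
                       call. = FALSE))
  # only overwrite the bases this site controls, so L1014F and L1014H can
  # both mark codon 1014 without clobbering each other
  chars <- seq_chars(codon)
  wild <- seq_chars(site$wild_codon)
  for (k in 1:3) {
    if (chars[k] != wild[k] || genotype == "SS") {
      substr(seqn, start + k - 1L, start + k - 1L) <- chars[k]
    }
  }
  seqn
}

#' Render consensus sequences for simulated genotypes
#'
#' Writes, per individual, the synthetic reference with each site's codon
#' set according to its genotype; heterozygotes get the IUPAC code whose
#' expansion is exactly \{wild, mutant\} at the variable position (a Sanger
#' consensus double peak). The gDNA form carries the intron between the
#' 918/929 region and the 1014 region; the cDNA form is contiguous.
#'
#' @param truth A data.frame with column `id` plus one column per site name
#'   (values `"SS"`, `"RS"`, `"RR"`); omitted sites render wild-type.
#' @param form `"cDNA"` or `"gDNA"`.
#' @param reference Optional reference list from [build_vssc_reference()];
#'   defaults to the packaged one.
#' @param path Optional FASTA output path.
#' @return A named character vector of sequences (invisibly when `path` is
#'   given).
#' @export
render_sequences <- function(truth, form = c("cDNA", "gDNA"),
                             reference = NULL, path = NULL) {
  form <- match.arg(form)
  if (is.null(reference)) reference <- packaged_reference()
  sites <- builtin_sites()
  names(sites) <- vapply(sites, `[[`, character(1L), "name")
  site_cols <- intersect(names(truth), names(sites))
  if (!"id" %in% names(truth)) stop("truth needs an 'id' column",
                                    call. = FALSE)
  seqs <- vapply(seq_len(nrow(truth)), function(i) {
    s <- reference$cdna
    for (nm in site_cols) {
      g <- truth[[nm]][i]
      if (is.na(g) || g == "SS") next
      s <- substitute_codon(s, reference$codon_starts[[nm]], sites[[nm]], g)
    }
    if (form == "gDNA") {
      s <- paste0(substr(s, 1L, reference$intron_after), reference$intron,
                  substr(s, reference$intron_after + 1L, nchar(s)))
    }
    s
  }, character(1L))
  names(seqs) <- truth$id
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
    return(invisible(seqs))
  }
  seqs
}

packaged_reference <- function() {
  if (is.null(.pkg_env$reference)) {
    .pkg_env$reference <- build_vssc_reference()
  }
  .pkg_env$reference
}

#' Render the two haplotypes of a simulated diploid
#'
#' PASA amplifies each chromosome copy separately, so the band simulator
#' needs haplotypes rather than an ambiguity-coded consensus. Heterozygous
#' sites place the mutant allele on haplotype A and the wild allele on
#' haplotype B (phase is arbitrary and irrelevant to band patterns).
#'
#' @param genotypes Named character vector, site name -> genotype.
#' @param form `"cDNA"` or `"gDNA"`.
#' @param reference Optional [build_vssc_reference()] result.
#' @return A [diploid_template()].
#' @export
render_haplotypes <- function(genotypes, form = c("cDNA", "gDNA"),
                              reference = NULL) {
  form <- match.arg(form)
  split_hap <- function(which_hap) {
    g <- vapply(genotypes, function(x) {
      switch(x, RR = "RR", SS = "SS",
             RS = if (which_hap == "a") "RR" else "SS",
             stop("cannot render genotype '", x, "'", call. = FALSE))
    }, character(1L))
    truth <- as.data.frame(as.list(g), optional = TRUE)
    truth$id <- which_hap
    render_sequences(truth, form = form, reference = reference)[[1L]]
  }
  diploid_template(split_hap("a"), split_hap("b"))
}

default_kill_curves <- function() {
  list(susceptible = list(midpoint = 30, slope = 8, t100 = 60),
       resistant = list(midpoint = 55, slope = 12, t100 = 90))
}

kill_probability <- function(times, curve) {
  p <- stats::plogis((times - curve$midpoint) / curve$slope)
  cap <- curve$cap %||% 1
  p <- pmin(p, cap)
  if (is.finite(curve$t100 %||% Inf)) p[times >= curve$t100] <- 1
  cummax(p)
}

#' Simulate a bottle-bioassay run
#'
#' Cumulative kill probability follows a logistic in time, clamped to 100%
#' at the curve's `t100` (60 min for the susceptible profile, 90 min for
#' the resistant one, mirroring the packaged survey's patterns). In
#' deterministic mode deaths are the rounded expectation; in stochastic
#' mode incremental deaths are drawn binomially from the survivors with the
#' conditional hazard, so series are always monotone. The control bottle
#' has zero mortality by default.
#'
#' @param status `"susceptible"` or `"resistant"`.
#' @param dose Dose in ug/ml (default 4.5).
#' @param n_bottles Treated bottles (default 4).
#' @param n_insects Insects per bottle (default 25).
#' @param times Observation grid (default 0-120 by 15 min).
#' @param curve Optional `list(midpoint =, slope =, t100 =, cap =)`
#'   overriding the per-status default.
#' @param stochastic Draw binomial deaths instead of the expectation.
#' @param seed Optional integer seed (local to this call).
#' @param location Location label.
#' @param date Date label.
#' @return An [assay_run()].
#' @export
simulate_bioassay <- function(status = c("susceptible", "resistant"),
                              dose = 4.5, n_bottles = 4L, n_insects = 25L,
                              times = DEFAULT_TIME_GRID, curve = NULL,
                              stochastic = FALSE, seed = NULL,
                              location = status, date = NA_character_) {
  status <- match.arg(status)
  location <- location[1L]
  curve <- curve %||% default_kill_curves()[[status]]
  p <- kill_probability(times, curve)
  make_bottle <- function(i) {
    dead <- if (!stochastic) {
      as.integer(round(n_insects * p))
    } else {
      d <- integer(length(times))
      alive <- n_insects
      prev <- 0
      for (k in seq_along(times)) {
        hz <- if (prev >= 1) 1 else (p[k] - prev) / (1 - prev)
        new_dead <- stats::rbinom(1L, alive, max(0, min(1, hz)))
        if (p[k] >= 1) new_dead <- alive
        d[k] <- (n_insects - alive) + new_dead
        alive <- alive - new_dead
        prev <- p[k]
      }
      d
    }
    mortality_series(sprintf("%s_T%d", location, i), location, dose,
                     n_insects, times, dead)
  }
  build <- function() {
    treated <- lapply(seq_len(n_bottles), make_bottle)
    control <- mortality_series(paste0(location, "_C"), location, 0,
                                n_insects, times, rep(0L, length(times)))
    assay_run(location, treated, control, date = date)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Synthetic susceptible-strain dose ladder
#'
#' Four doses engineered so that the two lowest never reach complete kill,
#' 4.5 ug/ml first reaches 100% in all bottles at 60 min, and the top dose
#' kills faster — reproducing a diagnostic of (4.5 ug/ml, 60 min) via
#' [diagnostic_from_susceptible()].
#'
#' @param doses Dose ladder (ug/ml).
#' @param stochastic,seed Passed to [simulate_bioassay()].
#' @return List of [assay_run()] objects, one per dose.
#' @export
simulate_susceptible_panel <- function(doses = c(1.125, 2.25, 4.5, 9),
                                       stochastic = FALSE, seed = NULL) {
  curves <- list(
    `1.125` = list(midpoint = 90, slope = 20, t100 = Inf, cap = 0.95),
    `2.25` = list(midpoint = 70, slope = 15, t100 = Inf, cap = 0.98),
    `4.5` = default_kill_curves()$susceptible,
    `9` = list(midpoint = 12, slope = 5, t100 = 30))
  lapply(seq_along(doses), function(i) {
    key <- as.character(doses[i])
    simulate_bioassay("susceptible", dose = doses[i],
                      curve = curves[[key]] %||% curves[["4.5"]],
                      stochastic = stochastic,
                      seed = if (is.null(seed)) NULL else seed + i,
                      location = paste0("susceptible_dose_", key))
  })
}
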