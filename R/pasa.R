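# In-silico PASA (PCR Amplification of Specific Alleles): primer binding
# with 3'-terminal allele discrimination, amplicon prediction from diploid
# templates, and gel band-pattern interpretation.

#' Define a PCR primer
#'
#' @param name Primer name, e.g. `"kdr1"`.
#' @param sequence 5'-3' unambiguous nucleotide string.
#' @param declared_direction `"forward"` or `"reverse"` as published
#'   (metadata; binding-site search covers both orientations and the
#'   productive orientation is whichever yields a facing pair).
#' @param annealing_temp Annealing temperature in degrees C (metadata).
#' @return An object of class `primer`.
#' @export
primer <- function(name, sequence, declared_direction = c("forward",
                                                          "reverse"),
                   annealing_temp = NA_real_) {
  declared_direction <- match.arg(declared_direction)
  sequence <- clean_sequence(sequence, paste0("primer ", name))
  if (!all(seq_chars(sequence) %in% c("A", "C", "G", "T"))) {
    stop("primer '", name, "' must contain only unambiguous bases",
         call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 declared_direction = declared_direction,
                 annealing_temp = annealing_temp),
            class = "primer")
}

#' Define the three-reaction PASA assay
#'
#' The assay runs three PCRs per insect: a control pair amplifying in every
#' genotype, a susceptible-specific pair and a resistant-specific pair. Each
#' value of `pairs` names two primers from `primers`. `expected_sizes` are
#' the nominal gel band sizes used for interpretation; a measured (or
#' predicted) band matches an expected size when within `size_tolerance`
#' (relative).
#'
#' @param primers Named list of [primer()] objects.
#' @param pairs Named list (`control`, `susceptible`, `resistant`) of
#'   2-vectors of primer names.
#' @param expected_sizes Named numeric (`control`, `susceptible`,
#'   `resistant`), distinct positive bp values.
#' @param size_tolerance Relative tolerance for band matching (default 0.10,
#'   i.e. +/-10% — gel sizing is approximate).
#' @return An object of class `assay_definition`.
#' @export
assay_definition <- function(primers, pairs, expected_sizes,
                             size_tolerance = 0.10) {
  stopifnot(is.list(primers),
            all(vapply(primers, inherits, logical(1L), "primer")))
  names(primers) <- vapply(primers, `[[`, character(1L), "name")
  need <- c("control", "susceptible", "resistant")
  if (!all(need %in% names(pairs)) || !all(need %in% names(expected_sizes))) {
    stop("'pairs' and 'expected_sizes' need entries control, susceptible, ",
         "resistant", call. = FALSE)
  }
  for (rx in need) {
    if (length(pairs[[rx]]) != 2L || !all(pairs[[rx]] %in% names(primers))) {
      stop("reaction '", rx, "' must name two known primers", call. = FALSE)
    }
  }
  expected_sizes <- unlist(expected_sizes)[need]
  if (any(expected_sizes <= 0) || anyDuplicated(expected_sizes)) {
    stop("expected sizes must be positive and distinct", call. = FALSE)
  }
  if (size_tolerance < 0 || size_tolerance >= 1) {
    stop("size_tolerance must be in [0, 1)", call. = FALSE)
  }
  structure(list(primers = primers, pairs = lapply(pairs[need], as.character),
                 expected_sizes = expected_sizes,
                 size_tolerance = size_tolerance),
            class = "assay_definition")
}

assay_from_config <- function(cfg) {
  primers <- lapply(cfg$primers, function(p) {
    primer(p$name, p$sequence, tolower(p$declared_direction %||% "forward"),
           p$annealing_temp %||% NA_real_)
  })
  assay_definition(primers, cfg$pairs, unlist(cfg$expected_sizes),
                   cfg$size_tolerance %||% 0.10)
}

assay_to_config <- function(assay) {
  list(primers = lapply(unname(assay$primers), function(p) {
         list(name = p$name, sequence = p$sequence,
              declared_direction = p$declared_direction,
              annealing_temp = p$annealing_temp)
       }),
       pairs = assay$pairs,
       expected_sizes = as.list(assay$expected_sizes),
       size_tolerance = assay$size_tolerance)
}

#' The packaged PASA assay definition
#'
#' Four primers (kdr1-kdr4), reactions kdr1+kdr4 (control, nominal 480 bp),
#' kdr1+kdr3 (susceptible-specific, nominal 200 bp) and kdr2+kdr4
#' (resistant-specific, nominal 280 bp).
#'
#' @return An [assay_definition()].
#' @export
default_assay <- function() {
  assay <- default_gene_model()$assay
  if (is.null(assay)) stop("packaged model has no assay", call. = FALSE)
  assay
}

#' Find primer binding sites on a template
#'
#' A site is a window (on either strand) where the primer's 3'-terminal
#' `three_prime_exact` bases match the template exactly — the
#' allele-discrimination mechanism of PASA — and at most
#' `max_internal_mismatches` of the remaining bases mismatch (a primer base
#' absent from the IUPAC expansion of the template base).
#'
#' @param template Nucleotide sequence (string).
#' @param primer A [primer()].
#' @param three_prime_exact Number of 3'-terminal bases requiring an exact
#'   match (default 1).
#' @param max_internal_mismatches Maximum mismatches elsewhere (default 0).
#' @return A data.frame of sites: `primer`, `start`, `end` (1-based,
#'   inclusive, forward-template coordinates), `strand` (`"+"` primes
#'   rightward, `"-"` leftward), `mismatches`, `three_prime` (forward
#'   coordinate of the primer's 3' base). Empty when the primer cannot
#'   prime.
#' @export
find_binding_sites <- function(template, primer, three_prime_exact = 1L,
                               max_internal_mismatches = 0L) {
  template <- clean_sequence(template, "template")
  p <- seq_chars(primer$sequence)
  L <- length(p)
  if (three_prime_exact < 1L || three_prime_exact > L) {
    stop("three_prime_exact must be in 1..primer length", call. = FALSE)
  }
  tp_idx <- (L - three_prime_exact + 1L):L
  n <- nchar(template)
  out <- list()
  scan_one <- function(chars) {
    if (n < L) return(NULL)
    nw <- n - L + 1L
    M <- base_match_matrix()
    internal <- integer(nw)
    exact3 <- rep(TRUE, nw)
    for (i in seq_len(L)) {
      window <- chars[i:(i + nw - 1L)]
      if (i %in% tp_idx) {
        exact3 <- exact3 & (window == p[i])
      } else {
        internal <- internal + !M[p[i], window]
      }
    }
    which(exact3 & internal <= max_internal_mismatches)
  }
  fchars <- seq_chars(template)
  fhits <- scan_one(fchars)
  if (length(fhits)) {
    out[["+"]] <- data.frame(primer = primer$name, start = fhits,
                             end = fhits + L - 1L, strand = "+",
                             mismatches = NA_integer_,
                             three_prime = fhits + L - 1L,
                             stringsAsFactors = FALSE)
  }
  rchars <- seq_chars(revcomp(template))
  rhits <- scan_one(rchars)
  if (length(rhits)) {
    # convert reverse-frame window [s, s+L-1] to forward coordinates
    fstart <- n - (rhits + L - 1L) + 1L
    out[["-"]] <- data.frame(primer = primer$name, start = fstart,
                             end = fstart + L - 1L, strand = "-",
                             mismatches = NA_integer_,
                             three_prime = fstart,
                             stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(primer = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), three_prime = integer(),
                      stringsAsFactors = FALSE))
  }
  sites <- do.call(rbind, out)
  # fill in counted internal mismatches for reporting
  M <- base_match_matrix()
  sites$mismatches <- vapply(seq_len(nrow(sites)), function(k) {
    chars <- if (sites$strand[k] == "+") fchars else rchars
    s <- if (sites$strand[k] == "+") sites$start[k]
         else n - sites$end[k] + 1L
    sum(!M[cbind(p[-tp_idx], chars[(s:(s + L - 1L))[-tp_idx]])])
  }, integer(1L))
  rownames(sites) <- NULL
  sites
}

#' Construct a diploid template
#'
#' @param haplotype_a,haplotype_b Nucleotide sequences, one per chromosome
#'   copy (identical for homozygotes).
#' @return An object of class `diploid_template`.
#' @export
diploid_template <- function(haplotype_a, haplotype_b = haplotype_a) {
  structure(list(haplotype_a = clean_sequence(haplotype_a, "haplotype_a"),
                 haplotype_b = clean_sequence(haplotype_b, "haplotype_b")),
            class = "diploid_template")
}

#' Predict PASA gel bands from a diploid template
#'
#' For each of the three reactions, every pairing of a rightward-priming
#' site with a leftward-priming site (from either primer of the pair) that
#' faces it within `max_product_length` produces an amplicon per haplotype;
#' the band pattern is the union of product sizes (end-to-end inclusive
#' length) over both haplotypes.
#'
#' @param template A [diploid_template()] (or a single sequence, treated as
#'   homozygous).
#' @param assay An [assay_definition()].
#' @param insect_id Identifier for the returned pattern.
#' @param max_product_length Longest amplicon considered (default 3000 bp).
#' @param three_prime_exact,max_internal_mismatches Passed to
#'   [find_binding_sites()].
#' @return A `band_pattern`: list with `insect_id` and sorted integer
#'   `band_sizes`.
#' @export
predict_bands <- function(template, assay = default_assay(),
                          insect_id = "insect", max_product_length = 3000L,
                          three_prime_exact = 1L,
                          max_internal_mismatches = 0L) {
  if (!inherits(template, "diploid_template")) {
    template <- diploid_template(template)
  }
  haps <- c(template$haplotype_a, template$haplotype_b)
  sizes <- integer()
  for (rx in names(assay$pairs)) {
    prs <- assay$primers[assay$pairs[[rx]]]
    for (hap in unique(haps)) {
      sites <- do.call(rbind, lapply(prs, find_binding_sites,
                                     template = hap,
                                     three_prime_exact = three_prime_exact,
                                     max_internal_mismatches =
                                       max_internal_mismatches))
      fwd <- sites[sites$strand == "+", , drop = FALSE]
      rev <- sites[sites$strand == "-", , drop = FALSE]
      if (!nrow(fwd) || !nrow(rev)) next
      for (i in seq_len(nrow(fwd))) {
        for (j in seq_len(nrow(rev))) {
          if (rev$start[j] <= fwd$end[i]) {
            if (rev$end[j] >= fwd$start[i]) {
              stop("assay-geometry error in reaction '", rx,
                   "': primer sites ", fwd$primer[i], " and ",
                   rev$primer[j], " overlap", call. = FALSE)
            }
            next  # reverse site entirely upstream: not facing
          }
          size <- rev$end[j] - fwd$start[i] + 1L
          if (size > 0L && size <= max_product_length) {
            sizes <- c(sizes, size)
          }
        }
      }
    }
  }
  band_pattern(insect_id, sizes)
}

#' Construct a band pattern
#'
#' @param insect_id Insect identifier.
#' @param band_sizes Integer band sizes in bp (positive; duplicates and
#'   order ignored).
#' @return An object of class `band_pattern`.
#' @export
band_pattern <- function(insect_id, band_sizes) {
  band_sizes <- sort(unique(as.integer(band_sizes)))
  if (any(band_sizes <= 0L)) stop("band sizes must be positive", call. = FALSE)
  structure(list(insect_id = insect_id, band_sizes = band_sizes),
            class = "band_pattern")
}

match_band <- function(size, assay) {
  rel <- abs(size - assay$expected_sizes) / assay$expected_sizes
  if (min(rel) <= assay$size_tolerance) names(which.min(rel))
  else NA_character_
}

#' Interpret a gel band pattern as a genotype
#'
#' Bands are matched to the assay's expected sizes within the relative
#' `size_tolerance`; unmatched bands are ignored with a warning. The
#' interpretation rule: with the control band present, the
#' resistant-specific band alone calls RR, the susceptible-specific band
#' alone calls SS, and both together call RS. Without a control band the
#' reaction failed and the call is INDETERMINATE regardless of other bands,
#' as is a control band with neither allele-specific product.
#'
#' @param pattern A [band_pattern()].
#' @param assay An [assay_definition()].
#' @return A list: `insect_id`, `genotype`, `matched` (named vector mapping
#'   expected band to the observed size, NA when absent), `ignored`
#'   (unmatched observed sizes).
#' @examples
#' genotype_from_bands(band_pattern("fly", c(480, 280, 200)))$genotype # "RS"
#' @export
genotype_from_bands <- function(pattern, assay = default_assay()) {
  matched <- stats::setNames(rep(NA_integer_, 3L),
                             c("control", "susceptible", "resistant"))
  ignored <- integer()
  for (size in pattern$band_sizes) {
    hit <- match_band(size, assay)
    if (is.na(hit)) {
      ignored <- c(ignored, size)
    } else if (is.na(matched[hit])) {
      matched[hit] <- size
    } else {
      ignored <- c(ignored, size)
    }
  }
  if (length(ignored)) {
    warning("insect '", pattern$insect_id, "': band(s) ",
            paste(ignored, collapse = ", "),
            " bp match no expected size; ignored", call. = FALSE)
  }
  genotype <- if (is.na(matched["control"])) {
    INDETERMINATE
  } else if (!is.na(matched["resistant"]) && !is.na(matched["susceptible"])) {
    "RS"
  } else if (!is.na(matched["resistant"])) {
    "RR"
  } else if (!is.na(matched["susceptible"])) {
    "SS"
  } else {
    INDETERMINATE
  }
  list(insect_id = pattern$insect_id, genotype = genotype,
       matched = matched, ignored = ignored)
}

#' Expected band set for a genotype
#'
#' Inverse of the gel interpretation table, using the assay's nominal
#' expected sizes.
#'
#' @param genotype `"SS"`, `"RS"` or `"RR"`.
#' @param assay An [assay_definition()].
#' @return Integer vector of expected band sizes (bp), sorted.
#' @export
bands_for_genotype <- function(genotype, assay = default_assay()) {
  if (!is.character(genotype) || length(genotype) != 1L ||
      !genotype %in% GENOTYPES) {
    stop("genotype must be one of ", paste(GENOTYPES, collapse = ", "),
         call. = FALSE)
  }
  sz <- assay$expected_sizes
  sort(as.integer(switch(genotype,
                         SS = sz[c("control", "susceptible")],
                         RR = sz[c("control", "resistant")],
                         RS = sz)))
}

#' Read band patterns from CSV
#'
#' Expects columns `insect_id` and `band_sizes`, the latter a
#' semicolon-separated list of sizes in bp (e.g. `"480;280;200"`).
#'
#' @param path CSV path ('#' comment lines allowed).
#' @return A list of [band_pattern()] objects.
#' @export
read_band_patterns <- function(path) {
  df <- read_table_csv(path, "band-pattern CSV")
  stop_if_missing_cols(df, c("insect_id", "band_sizes"), "band-pattern CSV")
  lapply(seq_len(nrow(df)), function(i) {
    sizes <- as.integer(strsplit(as.character(df$band_sizes[i]),
                                 "[;| ]+")[[1L]])
    band_pattern(df$insect_id[i], sizes)
  })
}
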