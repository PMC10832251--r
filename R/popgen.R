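# Population screening statistics: allele counts and frequencies, the fixed
# per-location allele percentage used in the survey table, Hardy-Weinberg
# chi-square tests, and per-location plus aggregate summaries.

#' Construct a per-location genotype count table
#'
#' @param location Character vector of location names.
#' @param n_RR,n_RS,n_SS Non-negative integer genotype counts (homozygous
#'   resistant, heterozygous, homozygous susceptible).
#' @return A `genotype_counts` data.frame with an `N` column.
#' @export
genotype_counts <- function(location, n_RR, n_RS, n_SS) {
  if (!(length(location) == length(n_RR) && length(n_RR) == length(n_RS) &&
        length(n_RS) == length(n_SS))) {
    stop("all arguments must have the same length", call. = FALSE)
  }
  for (v in list(n_RR, n_RS, n_SS)) {
    if (!all(vapply(v, is_count, logical(1L)))) {
      stop("genotype counts must be non-negative integers", call. = FALSE)
    }
  }
  df <- data.frame(location = as.character(location),
                   n_RR = as.integer(n_RR), n_RS = as.integer(n_RS),
                   n_SS = as.integer(n_SS), stringsAsFactors = FALSE)
  df$N <- df$n_RR + df$n_RS + df$n_SS
  class(df) <- c("genotype_counts", "data.frame")
  df
}

#' Read per-location genotype counts from CSV
#'
#' Expects columns `location`, `n_RR`, `n_RS`, `n_SS`.
#'
#' @param path CSV path ('#' comment lines allowed).
#' @return A [genotype_counts()] data.frame.
#' @export
read_genotype_counts <- function(path) {
  df <- read_table_csv(path, "genotype-count CSV")
  stop_if_missing_cols(df, c("location", "n_RR", "n_RS", "n_SS"),
                       "genotype-count CSV")
  genotype_counts(df$location, df$n_RR, df$n_RS, df$n_SS)
}

#' Allele accounting for genotype counts
#'
#' Each RR insect carries two kdr alleles and each RS one, so
#' `kdr_count = 2 n_RR + n_RS`, `sus_count = 2 n_SS + n_RS`, and the kdr
#' allele frequency is `kdr_count / 2N`.
#'
#' @param counts A [genotype_counts()] data.frame (one or more rows).
#' @return `counts` with columns `kdr_count`, `sus_count`,
#'   `allele_frequency` appended.
#' @examples
#' allele_stats(genotype_counts("Mina Zayed", 1, 9, 6))
#' @export
allele_stats <- function(counts) {
  if (any(counts$N < 1L)) {
    stop("each location needs N >= 1 insect", call. = FALSE)
  }
  counts$kdr_count <- 2L * counts$n_RR + counts$n_RS
  counts$sus_count <- 2L * counts$n_SS + counts$n_RS
  counts$allele_frequency <- counts$kdr_count / (2 * counts$N)
  counts
}

#' kdr allele percentage with a fixed allele denominator
#'
#' The survey table reports "% RR alleles" as `kdr_count` over a fixed
#' denominator of 32 allele copies (a nominal 16 flies per site) for every
#' location, rather than over the location's `2N`. This function reproduces
#' that convention; pass `denominator_alleles = 2 * counts$N` for the
#' standard frequency times 100. Values are rounded half-up to one decimal,
#' matching the printed style.
#'
#' @param counts A [genotype_counts()] data.frame.
#' @param denominator_alleles Positive allele-count denominator (scalar or
#'   per-row); default 32.
#' @return Numeric vector of percentages, one per row.
#' @export
kdr_allele_percent <- function(counts, denominator_alleles = 32L) {
  if (any(denominator_alleles <= 0)) {
    stop("denominator_alleles must be positive", call. = FALSE)
  }
  kdr <- 2L * counts$n_RR + counts$n_RS
  round_half_up(kdr / denominator_alleles * 100, 1L)
}

#' Hardy-Weinberg equilibrium chi-square test for one location
#'
#' With kdr allele frequency `p = (2 n_RR + n_RS) / 2N` and `q = 1 - p`,
#' expected genotype counts are `N p^2`, `2 N p q`, `N q^2`; the statistic
#' is the plain Pearson chi-square over the three genotype classes with
#' **no** continuity correction, referred to a chi-square distribution with
#' 1 degree of freedom (3 classes − 1 − 1 estimated allele frequency).
#' Monomorphic samples (`p` 0 or 1) return `chi2 = 0` with an undefined
#' p-value and the `monomorphic` flag set; they carry no information about
#' equilibrium.
#'
#' @param counts A single-row [genotype_counts()] data.frame (or a list with
#'   `n_RR`, `n_RS`, `n_SS`).
#' @return An `hwe_result`: `chi2`, `p_value` (NA when monomorphic), `df`,
#'   `expected_RR`, `expected_RS`, `expected_SS`, `monomorphic`.
#' @examples
#' hwe_test(genotype_counts("Mina Zayed", 1, 9, 6))  # chi2 0.9742
#' @export
hwe_test <- function(counts) {
  if (is.data.frame(counts)) {
    if (nrow(counts) != 1L) {
      stop("hwe_test expects a single location; see summarize_populations()",
           call. = FALSE)
    }
    counts <- as.list(counts)
  }
  n_RR <- counts$n_RR; n_RS <- counts$n_RS; n_SS <- counts$n_SS
  N <- n_RR + n_RS + n_SS
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  p <- (2 * n_RR + n_RS) / (2 * N)
  q <- 1 - p
  expected <- c(RR = N * p^2, RS = 2 * N * p * q, SS = N * q^2)
  if (p == 0 || p == 1) {
    res <- list(chi2 = 0, p_value = NA_real_, df = 1L,
                expected_RR = expected[["RR"]],
                expected_RS = expected[["RS"]],
                expected_SS = expected[["SS"]], monomorphic = TRUE)
  } else {
    obs <- c(RR = n_RR, RS = n_RS, SS = n_SS)
    chi2 <- sum((obs - expected)^2 / expected)
    res <- list(chi2 = chi2,
                p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
                df = 1L,
                expected_RR = expected[["RR"]],
                expected_RS = expected[["RS"]],
                expected_SS = expected[["SS"]], monomorphic = FALSE)
  }
  structure(res, class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> chi2 = %.4f, df = %d, p = %s%s\n", x$chi2, x$df,
              if (is.na(x$p_value)) "-" else sprintf("%.4f", x$p_value),
              if (x$monomorphic) " (monomorphic)" else ""))
  invisible(x)
}

#' Per-location and aggregate population summary
#'
#' Computes, for every location, allele counts and frequency, the allele
#' percentage (standard `2N` denominator by default; set
#' `denominator_alleles = 32` to reproduce the survey table's fixed-
#' denominator column) and the HWE test; plus study-level aggregates:
#' overall genotype percentages, the number of locations carrying at least
#' one kdr allele, the percentage of locations with at least one RR insect,
#' and the number of polymorphic locations deviating from HWE at `alpha`
#' (monomorphic locations are excluded from the deviation denominator).
#'
#' @param table A [genotype_counts()] data.frame, one row per location.
#' @param alpha Significance level for HWE deviation (default 0.05).
#' @param denominator_alleles `NULL` (use each location's `2N`) or a fixed
#'   allele denominator such as 32.
#' @param bonferroni Apply a Bonferroni correction across locations before
#'   counting deviations (off by default; the packaged survey applies none).
#' @return A `population_summary`: list with `per_location` (data.frame) and
#'   `aggregate` (list).
#' @export
summarize_populations <- function(table, alpha = 0.05,
                                  denominator_alleles = NULL,
                                  bonferroni = FALSE) {
  if (!nrow(table)) stop("need at least one location", call. = FALSE)
  if (anyDuplicated(table$location)) {
    warning("duplicate location names in table", call. = FALSE)
  }
  per <- allele_stats(table)
  denom <- denominator_alleles %||% (2 * per$N)
  per$pct_kdr <- kdr_allele_percent(per, denom)
  hwe <- lapply(seq_len(nrow(per)), function(i) hwe_test(per[i, ]))
  per$chi2 <- vapply(hwe, `[[`, numeric(1L), "chi2")
  per$p_value <- vapply(hwe, `[[`, numeric(1L), "p_value")
  per$monomorphic <- vapply(hwe, `[[`, logical(1L), "monomorphic")
  thresh <- if (bonferroni) alpha / sum(!per$monomorphic) else alpha
  per$deviates_hwe <- !per$monomorphic & !is.na(per$p_value) &
    per$p_value < thresh
  tot <- colSums(per[, c("n_RR", "n_RS", "n_SS", "N")])
  aggregate <- list(
    n_locations = nrow(per),
    total_RR = unname(tot["n_RR"]), total_RS = unname(tot["n_RS"]),
    total_SS = unname(tot["n_SS"]), total_N = unname(tot["N"]),
    pct_RR = unname(tot["n_RR"] / tot["N"] * 100),
    pct_RS = unname(tot["n_RS"] / tot["N"] * 100),
    pct_SS = unname(tot["n_SS"] / tot["N"] * 100),
    n_locations_with_kdr = sum(per$kdr_count >= 1L),
    n_locations_with_RR = sum(per$n_RR >= 1L),
    pct_locations_with_RR = sum(per$n_RR >= 1L) / nrow(per) * 100,
    n_locations_deviating_hwe = sum(per$deviates_hwe),
    alpha = alpha
  )
  structure(list(per_location = per, aggregate = aggregate),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<population_summary> %d location(s), %d insects\n",
              a$n_locations, a$total_N))
  cat(sprintf("  genotypes: RR %d (%.1f%%), RS %d (%.1f%%), SS %d (%.1f%%)\n",
              a$total_RR, round_half_up(a$pct_RR), a$total_RS,
              round_half_up(a$pct_RS), a$total_SS, round_half_up(a$pct_SS)))
  cat(sprintf("  locations with kdr allele: %d/%d; with RR: %d/%d (%.1f%%)\n",
              a$n_locations_with_kdr, a$n_locations, a$n_locations_with_RR,
              a$n_locations, round_half_up(a$pct_locations_with_RR)))
  cat(sprintf("  deviating from HWE at alpha = %g: %d\n", a$alpha,
              a$n_locations_deviating_hwe))
  invisible(x)
}

#' Write a population summary as CSV
#'
#' Writes the per-location table and a one-row aggregate table. Numeric
#' columns keep full precision; display rounding is left to the caller.
#'
#' @param summary A [summarize_populations()] result.
#' @param per_location_path,aggregate_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_population_summary <- function(summary, per_location_path,
                                     aggregate_path) {
  utils::write.csv(summary$per_location, per_location_path,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(summary$aggregate), aggregate_path,
                   row.names = FALSE)
  invisible(c(per_location_path, aggregate_path))
}
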