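# Packaged worked example: a 19-location house fly genotype survey and a
# 16-location deltamethrin bottle-bioassay screen (Abu Dhabi, UAE, 2023),
# plus the writer that regenerates every packaged fixture file.

# Per-location PASA genotype counts with the published per-location
# statistics ("% RR alleles" over a fixed 32-allele denominator, HWE
# chi-square and p-value) kept verbatim for comparison. The Hili percentage
# is transcribed as published (15.6) although its own counts give 18.8
# under the fixed-32 convention; see the package vignette.
.survey_data <- function() {
  df <- data.frame(
    location = c("Mina Zayed", "Hadbat Al Zafranah", "Al Danah", "Al Muzoun",
                 "Al Mushrif", "Al Bateen", "Al Rawdah", "Shahama City",
                 "Al Samha", "Al Bahiya", "Baniyas", "Mirfa",
                 "Madinat Zayed", "Al Hayer", "Al Khazna", "Hili", "Remah",
                 "Central district", "Al Shuwaymah"),
    n_RR = c(1L, 0L, 0L, 1L, 1L, 0L, 4L, 0L, 0L, 1L, 1L, 1L, 2L, 1L, 0L,
             1L, 0L, 0L, 0L),
    n_SS = c(6L, 0L, 6L, 10L, 6L, 9L, 6L, 15L, 13L, 3L, 6L, 9L, 9L, 6L,
             13L, 15L, 8L, 11L, 12L),
    n_RS = c(9L, 6L, 13L, 4L, 3L, 6L, 7L, 3L, 5L, 4L, 1L, 4L, 7L, 2L, 4L,
             4L, 0L, 5L, 15L),
    pct_kdr_printed = c(34.4, 18.8, 40.6, 18.8, 15.6, 18.8, 46.9, 9.4,
                        15.6, 18.8, 9.4, 18.8, 34.4, 12.5, 12.5, 15.6,
                        0.0, 15.6, 46.9),
    chi2_printed = c(0.9741, 6, 5.1376, 0.4166, 0.4, 0.9375, 0.4623,
                     0.1487, 0.4682, 0.0355, 2.7823, 0.3213, 0.1259,
                     1.1479, 0.3022, 0.9304, 0, 0.5486, 3.994),
    p_printed = c(0.3236, 0.0143, 0.0234, 0.5186, 0.527, 0.3329, 0.4965,
                  0.6997, 0.4937, 0.8504, 0.0953, 0.5707, 0.7227, 0.2839,
                  0.5824, 0.3347, NA, 0.4588, 0.0456),
    stringsAsFactors = FALSE)
  df
}

#' Packaged genotype survey counts
#'
#' Per-location RR/RS/SS counts from the 2023 Abu Dhabi house fly survey
#' (19 locations, 279 flies screened for L1014F by PASA).
#'
#' @return A [genotype_counts()] data.frame.
#' @export
abudhabi_survey_counts <- function() {
  d <- .survey_data()
  genotype_counts(d$location, d$n_RR, d$n_RS, d$n_SS)
}

#' Published per-location statistics of the packaged survey
#'
#' The statistics as printed in the survey report: the "% RR alleles"
#' column (computed over a fixed 32-allele denominator), the HWE chi-square
#' and its p-value. Kept verbatim — including one internally inconsistent
#' percentage (Hili) — for reproduction tests.
#'
#' @return A data.frame: `location`, `pct_kdr_printed`, `chi2_printed`,
#'   `p_printed`.
#' @export
abudhabi_published_stats <- function() {
  .survey_data()[, c("location", "pct_kdr_printed", "chi2_printed",
                     "p_printed")]
}

# Bottle-bioassay screen: per-location status at the (4.5 ug/ml, 60 min)
# diagnostic, with time to 100% mortality.
.bioassay_outcomes <- function() {
  data.frame(
    location = c("Al Rawadah", "Al Mushrif", "Al Bateen", "Al Wathba",
                 "Al Falah", "Yas Island", "Mussafah Shabiya", "Al Adlah",
                 "Madinat Zayed", "Bida Bint Saud", "Al Shwaib", "Al Saa",
                 "Bu Kirayyah", "Malaqit", "Al Rawdah Al Sharqiyah",
                 "Al Aflaj"),
    date = c("10 March", "15 March", "1 April", "1 March", "3 March",
             "6 March", "8 March", "10 March", "16 March", "17 April",
             "28 April", "27 March", "1 March", "14 March", "11 April",
             "14 April"),
    status = c(rep("susceptible", 10L), "resistant",
               rep("susceptible", 4L), "resistant"),
    time_to_full = c(rep(60L, 10L), 90L, rep(60L, 4L), 90L),
    stringsAsFactors = FALSE)
}

#' Published bioassay outcomes of the packaged screen
#'
#' @return A data.frame: `location`, `date`, `status`, `time_to_full`
#'   (minutes to 100% mortality at 4.5 ug/ml deltamethrin).
#' @export
abudhabi_bioassay_outcomes <- function() {
  .bioassay_outcomes()
}

demo_truth_table <- function() {
  data.frame(
    id = sprintf("fly_%02d", 1:6),
    M918T = c("SS", "SS", "SS", "SS", "RS", "RR"),
    T929I = c("SS", "SS", "SS", "RS", "SS", "RR"),
    L1014F = c("SS", "RR", "RS", "RR", "SS", "SS"),
    L1014H = c("SS", "SS", "SS", "SS", "RS", "SS"),
    # Expected caller output differs from the designed genotype only where
    # an L1014F substitution destroys the L1014H site's wild context: a
    # TTT codon cannot be scored for L1014H.
    call_M918T = c("SS", "SS", "SS", "SS", "RS", "RR"),
    call_T929I = c("SS", "SS", "SS", "RS", "SS", "RR"),
    call_L1014F = c("SS", "RR", "RS", "RR", "SS", "SS"),
    call_L1014H = c("SS", "INDETERMINATE", "SS", "INDETERMINATE", "RS",
                    "SS"),
    stringsAsFactors = FALSE)
}

write_csv_with_header <- function(df, path, comment_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comment_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Regenerate every packaged fixture file
#'
#' Writes, into `dir`: the synthetic VSSC reference FASTA and gene-model
#' YAML, the genotype-survey CSV and its published statistics, the
#' bottle-bioassay mortality CSV (deterministic curves reproducing each
#' location's published status and time to 100% mortality), and a
#' six-individual demonstration FASTA with its truth table. All outputs
#' are deterministic; the packaged copies under `extdata` were produced by
#' this function.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
make_demo_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  add <- function(p) written <<- c(written, p)

  ref <- build_vssc_reference()
  fasta_path <- file.path(dir, "vssc_synthetic_reference.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(stats::setNames(
    ref$cdna,
    sprintf("Vssc_synthetic_cDNA synthetic reference (seed %d)",
            REFERENCE_SEED))), fasta_path)
  add(fasta_path)

  yaml_path <- file.path(dir, "vssc_gene_model.yaml")
  yaml::write_yaml(list(
    gene_name = "Vssc",
    reference_labels = list("NW_026712250.1 position 125581 (L1014F)",
                            "NM_001286885.1 (para-like mRNA)"),
    reference_fasta = "vssc_synthetic_reference.fasta",
    intron = list(after_position = ref$intron_after,
                  length = nchar(ref$intron)),
    sites = lapply(builtin_sites(), function(s) {
      unclass(s)[c("name", "codon_number", "wild_aa", "mutant_aa",
                   "wild_codon", "mutant_codon", "guide_sequence",
                   "codon_offset", "variable_position")]
    }),
    assay = list(
      primers = lapply(builtin_primers(), function(p) {
        list(name = p$name, sequence = p$sequence,
             declared_direction = p$declared_direction,
             annealing_temp = p$annealing_temp)
      }),
      pairs = list(control = c("kdr1", "kdr4"),
                   susceptible = c("kdr1", "kdr3"),
                   resistant = c("kdr2", "kdr4")),
      expected_sizes = list(control = 480L, susceptible = 200L,
                            resistant = 280L),
      size_tolerance = 0.10),
    sequencing_primers = list(
      list(name = "K1", sequence = "TCGCTTCAAGGACCATGAAT",
           declared_direction = "forward"),
      list(name = "K2", sequence = "TTACGTTTCACCCAGTTCTTA",
           declared_direction = "reverse"),
      list(name = "4Mut_kdr_F", sequence = "TCCGGAATTGGAGAAGGTGC",
           declared_direction = "forward"),
      list(name = "4Mut_kdr_R", sequence = "TCAAGCCATCGCCCATGATT",
           declared_direction = "reverse"))
  ), yaml_path)
  add(yaml_path)

  d <- .survey_data()
  add(write_csv_with_header(
    d[, c("location", "n_RR", "n_RS", "n_SS")],
    file.path(dir, "abudhabi2023_genotype_counts.csv"),
    c("Abu Dhabi 2023 house fly survey: per-location L1014F genotype",
      "counts from PASA (RR = kdr/kdr, RS = kdr/sus, SS = sus/sus)")))
  add(write_csv_with_header(
    d[, c("location", "pct_kdr_printed", "chi2_printed", "p_printed")],
    file.path(dir, "abudhabi2023_published_stats.csv"),
    c("Published per-location statistics of the Abu Dhabi 2023 survey,",
      "transcribed verbatim (pct over a fixed 32-allele denominator)")))

  outcomes <- .bioassay_outcomes()
  rows <- lapply(seq_len(nrow(outcomes)), function(i) {
    run <- simulate_bioassay(outcomes$status[i],
                             location = outcomes$location[i],
                             date = outcomes$date[i])
    bottles <- c(run$treated, list(run$control))
    do.call(rbind, lapply(bottles, function(s) {
      row <- data.frame(location = s$location, date = run$date,
                        bottle_id = s$bottle_id, dose_ug_ml = s$dose,
                        n_insects = s$n_insects, stringsAsFactors = FALSE)
      for (k in seq_along(s$times)) {
        row[[paste0("dead_", s$times[k])]] <- s$cumulative_dead[k]
      }
      row
    }))
  })
  add(write_csv_with_header(
    do.call(rbind, rows), file.path(dir, "abudhabi2023_bioassay.csv"),
    c("Abu Dhabi 2023 deltamethrin bottle bioassay; synthetic",
      "deterministic mortality curves reproducing each location's",
      "published status and time to 100% mortality at 4.5 ug/ml")))

  truth <- demo_truth_table()
  render_sequences(truth, form = "cDNA", reference = ref,
                   path = file.path(dir, "demo_flies_cdna.fasta"))
  add(file.path(dir, "demo_flies_cdna.fasta"))
  add(write_csv_with_header(
    truth, file.path(dir, "demo_flies_truth.csv"),
    c("Designed genotypes (and expected caller output) for the",
      "six-individual demonstration FASTA; deterministic rendering of the",
      sprintf("synthetic reference (seed %d)", REFERENCE_SEED))))

  invisible(written)
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata`, or `NULL` to list
#'   the available files.
#' @return A file path (or a vector of file names).
#' @examples
#' kdr_example()
#' kdr_example("abudhabi2023_genotype_counts.csv")
#' @export
kdr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "kdrscreen")))
  }
  system.file("extdata", file, package = "kdrscreen", mustWork = TRUE)
}
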