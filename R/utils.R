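# Internal helpers shared across modules.

.pkg_env <- new.env(parent = emptyenv())

GENOTYPES <- c("SS", "RS", "RR")
INDETERMINATE <- "INDETERMINATE"

iupac_map <- function() {
  if (is.null(.pkg_env$iupac)) {
    .pkg_env$iupac <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
  }
  .pkg_env$iupac
}

#' @noRd
expand_base <- function(base) {
  out <- iupac_map()[[base]]
  if (is.null(out)) {
    stop("not an IUPAC nucleotide code: '", base, "'", call. = FALSE)
  }
  out
}

# IUPAC code whose expansion is exactly `bases` (e.g. c("C","T") -> "Y")
ambiguity_code <- function(bases) {
  m <- iupac_map()
  key <- paste(sort(unique(bases)), collapse = "")
  for (nm in names(m)) {
    if (paste(sort(m[[nm]]), collapse = "") == key) return(nm)
  }
  stop("no IUPAC code for base set {", paste(bases, collapse = ","), "}",
       call. = FALSE)
}

# logical lookup: does unambiguous base g (row) match query code q (col),
# i.e. g is among the expansions of q
base_match_matrix <- function() {
  if (is.null(.pkg_env$match_mat)) {
    codes <- names(Biostrings::IUPAC_CODE_MAP)
    m <- matrix(FALSE, nrow = 4, ncol = length(codes),
                dimnames = list(c("A", "C", "G", "T"), codes))
    for (g in rownames(m)) {
      for (q in codes) m[g, q] <- g %in% expand_base(q)
    }
    .pkg_env$match_mat <- m
  }
  .pkg_env$match_mat
}

# Uppercase, U->T, strip whitespace, validate IUPAC alphabet.
clean_sequence <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  s <- toupper(gsub("[ \t\r\n]", "", x))
  s <- chartr("U", "T", s)
  if (nchar(s) == 0L) stop(what, " is empty", call. = FALSE)
  bad <- setdiff(unique(seq_chars(s)), names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0L) {
    stop(what, " contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Display rounding used throughout: half-up, matching how the survey tables
# print percentages (46.875 -> 46.9, which half-to-even would miss).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

stop_if_missing_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_table_csv <- function(path, what = "input CSV") {
  if (!file.exists(path)) stop("cannot read ", what, ": ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(what, " has no data rows: ", path, call. = FALSE)
  df
}
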