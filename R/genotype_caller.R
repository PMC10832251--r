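# Sequence-based genotyping: anchor a guide oligomer in a base-called
# consensus sequence (either strand), read the codon it marks, and call
# SS/RS/RR using IUPAC ambiguity codes for heterozygotes.

# Hamming scan of an unambiguous pattern over a (possibly ambiguous) query.
# A position matches when the pattern base is among the IUPAC expansions of
# the query base. `masked_idx` (0-based pattern indices) are skipped.
# Returns an integer vector of mismatch counts, one per window start.
scan_pattern <- function(query_chars, pattern_chars, masked_idx = integer()) {
  L <- length(pattern_chars)
  n <- length(query_chars)
  if (n < L) return(integer(0L))
  nw <- n - L + 1L
  mm <- integer(nw)
  M <- base_match_matrix()
  for (i in seq_len(L)) {
    if ((i - 1L) %in% masked_idx) next
    mm <- mm + !M[pattern_chars[i], query_chars[i:(i + nw - 1L)]]
  }
  mm
}

#' Locate a mutation site's guide anchor in a query sequence
#'
#' Slides the site's guide over the query (and, optionally, its reverse
#' complement) counting mismatches. Guide positions that fall on the marked
#' codon are excluded from the count, since those bases are genotype-
#' dependent. IUPAC codes in the query match any of their expansions.
#'
#' @param query Nucleotide sequence (string; IUPAC codes allowed).
#' @param site A [mutation_site()].
#' @param max_mismatches Maximum counted mismatches (default 1).
#' @param search_both_strands Also scan the reverse complement (default TRUE).
#' @return `NULL` when no window is within `max_mismatches`; otherwise a list
#'   with `site_name`, `position` (0-based start of the match on the forward
#'   query), `strand` (`"forward"` or `"reverse-complement"`), `mismatches`
#'   (counted, codon positions excluded) and `frame_position` (0-based start
#'   in the frame where the guide reads 5'-3'). Ties at the best mismatch
#'   count raise an ambiguity error listing the candidate positions.
#' @export
locate_anchor <- function(query, site, max_mismatches = 1L,
                          search_both_strands = TRUE) {
  query <- clean_sequence(query, "query")
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0", call. = FALSE)
  guide <- seq_chars(site$guide_sequence)
  L <- length(guide)
  masked <- guide_codon_overlap(site)
  qlen <- nchar(query)

  hits <- data.frame(frame_pos = integer(), strand = character(),
                     mismatches = integer())
  fwd <- scan_pattern(seq_chars(query), guide, masked)
  if (length(fwd)) {
    keep <- which(fwd <= max_mismatches)
    if (length(keep)) {
      hits <- rbind(hits, data.frame(frame_pos = keep - 1L,
                                     strand = "forward",
                                     mismatches = fwd[keep]))
    }
  }
  if (isTRUE(search_both_strands)) {
    rc <- scan_pattern(seq_chars(revcomp(query)), guide, masked)
    keep <- which(rc <= max_mismatches)
    if (length(keep)) {
      hits <- rbind(hits, data.frame(frame_pos = keep - 1L,
                                     strand = "reverse-complement",
                                     mismatches = rc[keep]))
    }
  }
  if (nrow(hits) == 0L) return(NULL)
  best <- hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
  if (nrow(best) > 1L) {
    pos_fwd <- ifelse(best$strand == "forward", best$frame_pos,
                      qlen - (best$frame_pos + L))
    stop("ambiguous anchor for site '", site$name, "': ", nrow(best),
         " equally good matches (", min(hits$mismatches),
         " mismatches) at forward positions ",
         paste(pos_fwd, collapse = ", "), call. = FALSE)
  }
  frame_pos <- best$frame_pos[1L]
  strand <- best$strand[1L]
  position <- if (strand == "forward") frame_pos else qlen - (frame_pos + L)
  list(site_name = site$name, position = position, strand = strand,
       mismatches = best$mismatches[1L], frame_position = frame_pos,
       query_length = qlen)
}

classify_codon <- function(codon_chars, site) {
  wild <- seq_chars(site$wild_codon)
  mut <- seq_chars(site$mutant_codon)
  vp <- site$variable_position
  # Non-variable positions: the wild base must be among the expansions of
  # the observed base (tolerant of overlapping heterozygosity from a
  # neighbouring mutation at the same codon, e.g. L1014F/L1014H).
  for (i in setdiff(1:3, vp)) {
    if (!wild[i] %in% expand_base(codon_chars[i])) return(INDETERMINATE)
  }
  vb <- codon_chars[vp]
  if (vb == wild[vp]) return("SS")
  if (vb == mut[vp]) return("RR")
  if (setequal(expand_base(vb), c(wild[vp], mut[vp]))) return("RS")
  INDETERMINATE
}

site_call <- function(site_name, observed_codon = NA_character_,
                      genotype = INDETERMINATE,
                      amino_acids = character(), evidence = NULL) {
  structure(list(site_name = site_name, observed_codon = observed_codon,
                 genotype = genotype, amino_acids = amino_acids,
                 evidence = evidence),
            class = "site_call")
}

#' Call the genotype at one mutation site from a consensus sequence
#'
#' Anchors the site's guide (either strand), extracts the codon at the
#' guide-relative offset and applies the genotype rule: at the variable
#' position, the wild base calls SS, the mutant base calls RR, and the IUPAC
#' code expanding to exactly \{wild, mutant\} calls RS. Anything else — a
#' third base, a wider ambiguity, a truncated codon or a missing anchor —
#' yields INDETERMINATE (a value, not an error).
#'
#' @inheritParams locate_anchor
#' @return A `site_call`: `site_name`, `observed_codon`, `genotype`
#'   (`"SS"`, `"RS"`, `"RR"` or `"INDETERMINATE"`), `amino_acids` (the
#'   translation set of the observed codon) and `evidence` (the anchor
#'   match, or `NULL`).
#' @examples
#' model <- default_gene_model()
#' call_site(model$reference_sequence, model$sites$L1014F)$genotype  # "SS"
#' @export
call_site <- function(query, site, max_mismatches = 1L,
                      search_both_strands = TRUE) {
  anchor <- locate_anchor(query, site, max_mismatches = max_mismatches,
                          search_both_strands = search_both_strands)
  if (is.null(anchor)) return(site_call(site$name))
  frame_seq <- if (anchor$strand == "forward") clean_sequence(query)
               else revcomp(clean_sequence(query))
  L <- nchar(site$guide_sequence)
  codon_start0 <- anchor$frame_position + L + site$codon_offset
  if (codon_start0 < 0L || codon_start0 + 3L > nchar(frame_seq)) {
    return(site_call(site$name, evidence = anchor))
  }
  codon <- substr(frame_seq, codon_start0 + 1L, codon_start0 + 3L)
  site_call(site$name, observed_codon = codon,
            genotype = classify_codon(seq_chars(codon), site),
            amino_acids = translate_codon(codon), evidence = anchor)
}

# Forward-frame 0-based codon start for a call with evidence, or NA.
call_codon_position <- function(call, site) {
  a <- call$evidence
  if (is.null(a)) return(NA_integer_)
  L <- nchar(site$guide_sequence)
  start_frame <- a$frame_position + L + site$codon_offset
  if (a$strand == "forward") start_frame
  else a$query_length - (start_frame + 3L)
}

#' Call every site of a gene model on one sequence
#'
#' Runs [call_site()] for each site. Per-site anchor ambiguity errors are
#' demoted to warnings (that site becomes INDETERMINATE) so one bad locus
#' does not abort the others. The input kind is inferred from anchor
#' geometry: when the 918/929-region and 1014-region anchors are separated
#' by at least the model's intron length the sequence is reported as gDNA,
#' when both regions are found closer together as cDNA, otherwise unknown.
#'
#' @param query Nucleotide sequence.
#' @param model A [gene_model()].
#' @param sequence_id Identifier used in reports.
#' @inheritParams locate_anchor
#' @return A `sequence_report`: list with `sequence_id`, `input_kind`
#'   (`"gDNA"`, `"cDNA"` or `"unknown"`) and `calls` (one `site_call` per
#'   site). Coerce with `as.data.frame()`.
#' @export
call_all_sites <- function(query, model, sequence_id = "query",
                           max_mismatches = 1L, search_both_strands = TRUE) {
  if (!length(model$sites)) stop("model has no sites", call. = FALSE)
  calls <- lapply(model$sites, function(site) {
    tryCatch(
      call_site(query, site, max_mismatches = max_mismatches,
                search_both_strands = search_both_strands),
      error = function(e) {
        warning("sequence '", sequence_id, "', site '", site$name, "': ",
                conditionMessage(e), call. = FALSE)
        site_call(site$name)
      })
  })
  # two informative heterozygous calls at one codon (e.g. L1014F + L1014H)
  # look like a compound heterozygote; both are reported, with a warning
  codon_nums <- vapply(model$sites, `[[`, integer(1L), "codon_number")
  gts <- vapply(calls, `[[`, character(1L), "genotype")
  for (cn in unique(codon_nums[duplicated(codon_nums)])) {
    if (sum(gts[codon_nums == cn] == "RS") >= 2L) {
      warning("sequence '", sequence_id, "': apparent compound ",
              "heterozygote at codon ", cn, "; both site calls reported, ",
              "no haplotype resolution attempted", call. = FALSE)
    }
  }
  pos <- mapply(call_codon_position, calls, model$sites)
  upstream <- pos[vapply(model$sites, `[[`, integer(1L),
                         "codon_number") < 1000L]
  downstream <- pos[vapply(model$sites, `[[`, integer(1L),
                           "codon_number") >= 1000L]
  intron_len <- (model$intron$length %||% 1700L)
  input_kind <- "unknown"
  if (any(!is.na(upstream)) && any(!is.na(downstream))) {
    gap <- min(downstream, na.rm = TRUE) - max(upstream, na.rm = TRUE)
    input_kind <- if (abs(gap) >= intron_len) "gDNA" else "cDNA"
  }
  structure(list(sequence_id = sequence_id, input_kind = input_kind,
                 calls = calls),
            class = "sequence_report")
}

#' @export
as.data.frame.sequence_report <- function(x, ...) {
  rows <- lapply(x$calls, function(cl) {
    ev <- cl$evidence
    data.frame(
      sequence_id = x$sequence_id,
      site = cl$site_name,
      codon = cl$observed_codon,
      genotype = cl$genotype,
      amino_acids = paste(cl$amino_acids, collapse = "/"),
      strand = if (is.null(ev)) NA_character_ else ev$strand,
      mismatches = if (is.null(ev)) NA_integer_ else ev$mismatches,
      anchor_position = if (is.null(ev)) NA_integer_ else ev$position + 1L,
      input_kind = x$input_kind,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sequence_report <- function(x, ...) {
  cat(sprintf("<sequence_report> %s (%s)\n", x$sequence_id, x$input_kind))
  print(as.data.frame(x)[, c("site", "codon", "genotype", "amino_acids",
                             "strand", "mismatches")])
  invisible(x)
}

#' Genotype every record of a FASTA file
#'
#' Reads a (multi-record, wrapped or unwrapped, case-insensitive) FASTA file
#' and calls all model sites on each record. Duplicate record ids get a
#' numeric suffix with a warning. Anchor positions are reported 1-based.
#'
#' @param path FASTA file with at least one record.
#' @param model A [gene_model()]; defaults to the packaged model.
#' @param sites Optional character vector restricting calls to these sites.
#' @inheritParams locate_anchor
#' @return A data.frame with one row per (record, site): columns
#'   `sequence_id`, `site`, `codon`, `genotype`, `amino_acids`, `strand`,
#'   `mismatches`, `anchor_position`, `input_kind`.
#' @export
genotype_fasta <- function(path, model = default_gene_model(), sites = NULL,
                           max_mismatches = 1L, search_both_strands = TRUE) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("cannot parse FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("FASTA has no records: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA record ids; suffixing", call. = FALSE)
    ids <- make.unique(ids, sep = "_dup")
  }
  if (!is.null(sites)) {
    unknown <- setdiff(sites, names(model$sites))
    if (length(unknown)) {
      stop("unknown site(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    model$sites <- model$sites[sites]
  }
  reports <- lapply(seq_along(set), function(i) {
    as.data.frame(call_all_sites(as.character(set[[i]]), model,
                                 sequence_id = ids[i],
                                 max_mismatches = max_mismatches,
                                 search_both_strands = search_both_strands))
  })
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}
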