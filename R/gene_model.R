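#' Define a VSSC mutation site
#'
#' A `mutation_site` describes one knockdown-resistance (kdr) mutation in the
#' house fly voltage-sensitive sodium channel (VSSC): the affected codon, the
#' wild-type and mutant codons, and a short guide (anchor) sequence used to
#' pinpoint the codon inside a sequenced fragment.
#'
#' The guide may overlap the codon itself. `codon_offset` gives the position
#' of the codon's first base relative to the *end* of the guide match
#' (0-based): `0` means the codon starts immediately after the guide,
#' `-1` means the guide's last base is the codon's first base, and so on.
#' The packaged sites use negative offsets because the published guides end
#' on the mutant base of the codon they mark.
#'
#' @param name Mutation label, e.g. `"L1014F"`.
#' @param codon_number Codon position in house fly *para* numbering.
#' @param wild_aa,mutant_aa One-letter amino acid codes.
#' @param wild_codon,mutant_codon Codons over A/C/G/T, differing at exactly
#'   one position.
#' @param guide_sequence Unambiguous anchor oligomer.
#' @param codon_offset Signed integer, see Details.
#' @param variable_position Which codon base (1-3) differs between wild and
#'   mutant.
#' @return An object of class `mutation_site`.
#' @examples
#' mutation_site("L1014F", 1014, "L", "F", "CTT", "TTT",
#'               "ACGGTCGTGATCGGCAATT", -1L, 1L)
#' @export
mutation_site <- function(name, codon_number, wild_aa, mutant_aa,
                          wild_codon, mutant_codon, guide_sequence,
                          codon_offset, variable_position) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("site 'name' must be a nonempty string", call. = FALSE)
  }
  if (!is_count(codon_number) || codon_number < 1) {
    stop("site '", name, "': 'codon_number' must be a positive integer",
         call. = FALSE)
  }
  wild_codon <- clean_sequence(wild_codon, paste0(name, " wild_codon"))
  mutant_codon <- clean_sequence(mutant_codon, paste0(name, " mutant_codon"))
  for (cd in c(wild_codon, mutant_codon)) {
    if (nchar(cd) != 3L || !all(seq_chars(cd) %in% c("A", "C", "G", "T"))) {
      stop("site '", name, "': codons must be unambiguous 3-mers",
           call. = FALSE)
    }
  }
  diff_pos <- which(seq_chars(wild_codon) != seq_chars(mutant_codon))
  if (length(diff_pos) != 1L) {
    stop("site '", name, "': wild and mutant codons must differ at exactly ",
         "one position (differ at ", length(diff_pos), ")", call. = FALSE)
  }
  if (!is_count(variable_position) || !(variable_position %in% 1:3)) {
    stop("site '", name, "': 'variable_position' must be 1, 2 or 3",
         call. = FALSE)
  }
  if (diff_pos != variable_position) {
    stop("site '", name, "': codons differ at position ", diff_pos,
         " but variable_position is ", variable_position, call. = FALSE)
  }
  guide_sequence <- clean_sequence(guide_sequence,
                                   paste0(name, " guide_sequence"))
  if (!all(seq_chars(guide_sequence) %in% c("A", "C", "G", "T"))) {
    stop("site '", name, "': guide_sequence must contain only unambiguous ",
         "bases", call. = FALSE)
  }
  if (!is.numeric(codon_offset) || length(codon_offset) != 1L ||
      is.na(codon_offset) || codon_offset != floor(codon_offset)) {
    stop("site '", name, "': 'codon_offset' must be an integer", call. = FALSE)
  }
  got_wild <- translate_codon(wild_codon)
  if (!identical(got_wild, toupper(wild_aa))) {
    stop("site '", name, "': wild_codon ", wild_codon, " translates to ",
         paste(got_wild, collapse = "/"), ", not ", wild_aa, call. = FALSE)
  }
  got_mut <- translate_codon(mutant_codon)
  if (!identical(got_mut, toupper(mutant_aa))) {
    stop("site '", name, "': mutant_codon ", mutant_codon, " translates to ",
         paste(got_mut, collapse = "/"), ", not ", mutant_aa, call. = FALSE)
  }
  structure(
    list(name = name, codon_number = as.integer(codon_number),
         wild_aa = toupper(wild_aa), mutant_aa = toupper(mutant_aa),
         wild_codon = wild_codon, mutant_codon = mutant_codon,
         guide_sequence = guide_sequence,
         codon_offset = as.integer(codon_offset),
         variable_position = as.integer(variable_position)),
    class = "mutation_site"
  )
}

# 0-based indices *within the guide* that fall on the codon (excluded from
# anchor mismatch counting; the codon is genotype-dependent).
guide_codon_overlap <- function(site) {
  L <- nchar(site$guide_sequence)
  codon_idx <- (L + site$codon_offset):(L + site$codon_offset + 2L)
  codon_idx[codon_idx >= 0L & codon_idx < L]
}

#' @export
print.mutation_site <- function(x, ...) {
  cat(sprintf("<mutation_site> %s: codon %d %s(%s) -> %s(%s), guide %s (offset %d, variable pos %d)\n",
              x$name, x$codon_number, x$wild_aa, x$wild_codon, x$mutant_aa,
              x$mutant_codon, x$guide_sequence, x$codon_offset,
              x$variable_position))
  invisible(x)
}

#' Assemble a VSSC gene model
#'
#' Bundles the mutation sites, an optional reference sequence on which every
#' guide must anchor uniquely, an optional gDNA intron descriptor, and an
#' optional PASA assay definition.
#'
#' @param gene_name Gene symbol, e.g. `"Vssc"`.
#' @param sites List of [mutation_site()] objects with unique names.
#' @param reference_labels Free-text coordinate labels for provenance.
#' @param reference_sequence Optional nucleotide string; when present every
#'   guide must have a unique anchor on it (codon positions are ignored when
#'   counting guide mismatches, see [locate_anchor()]).
#' @param intron Optional `list(after_position =, length =)`: in the gDNA
#'   form an intron of `length` bases sits after coding position
#'   `after_position` (1-based), between the 918/929 region and the 1014
#'   region.
#' @param assay Optional [assay_definition()].
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_name, sites, reference_labels = character(),
                       reference_sequence = NULL, intron = NULL,
                       assay = NULL) {
  if (!length(sites)) stop("a gene model needs at least one site", call. = FALSE)
  if (!all(vapply(sites, inherits, logical(1L), "mutation_site"))) {
    stop("'sites' must be a list of mutation_site objects", call. = FALSE)
  }
  nms <- vapply(sites, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("site names must be unique; duplicated: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sites) <- nms
  if (!is.null(reference_sequence)) {
    reference_sequence <- clean_sequence(reference_sequence,
                                         "reference_sequence")
  }
  if (!is.null(intron)) {
    if (!is.list(intron) || !is_count(intron$after_position %||% -1) ||
        !is_count(intron$length %||% -1)) {
      stop("'intron' must be list(after_position =, length =) of ",
           "non-negative integers", call. = FALSE)
    }
    intron$after_position <- as.integer(intron$after_position)
    intron$length <- as.integer(intron$length)
  }
  model <- structure(
    list(gene_name = gene_name, sites = sites,
         reference_labels = as.character(reference_labels),
         reference_sequence = reference_sequence,
         intron = intron, assay = assay),
    class = "gene_model"
  )
  if (!is.null(reference_sequence)) {
    for (site in sites) {
      hit <- tryCatch(
        locate_anchor(reference_sequence, site, max_mismatches = 0L,
                      search_both_strands = FALSE),
        error = function(e) {
          stop("guide for site '", site$name, "' is ambiguous on the ",
               "reference sequence: ", conditionMessage(e), call. = FALSE)
        })
      if (is.null(hit)) {
        stop("guide for site '", site$name, "' does not occur on the ",
             "coding strand of the reference sequence", call. = FALSE)
      }
    }
  }
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s: %d site(s)%s%s\n", x$gene_name,
              length(x$sites),
              if (!is.null(x$reference_sequence))
                sprintf(", reference %d bp", nchar(x$reference_sequence))
              else "",
              if (!is.null(x$intron))
                sprintf(", intron %d bp after position %d", x$intron$length,
                        x$intron$after_position)
              else ""))
  for (s in x$sites) print(s)
  invisible(x)
}

site_field_spec <- c(name = "character", codon_number = "integer",
                     wild_aa = "character", mutant_aa = "character",
                     wild_codon = "character", mutant_codon = "character",
                     guide_sequence = "character", codon_offset = "integer",
                     variable_position = "integer")

#' Load a gene model from a YAML config
#'
#' The config declares the gene name, the mutation sites (all
#' [mutation_site()] fields), and optionally a reference FASTA (path
#' relative to the config file), an intron descriptor and the PASA assay.
#' See the packaged `vssc_gene_model.yaml` for the schema.
#'
#' @param path Path to a YAML gene-model config.
#' @return A validated [gene_model()].
#' @seealso [default_gene_model()], [write_gene_model()]
#' @export
load_gene_model <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sites) || !length(cfg$sites)) {
    stop("configuration error: 'sites' must declare at least one site",
         call. = FALSE)
  }
  sites <- lapply(cfg$sites, function(s) {
    missing <- setdiff(names(site_field_spec), names(s))
    if (length(missing)) {
      stop("configuration error in site '", s$name %||% "<unnamed>",
           "': missing field(s) ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    mutation_site(s$name, s$codon_number, s$wild_aa, s$mutant_aa,
                  s$wild_codon, s$mutant_codon, s$guide_sequence,
                  s$codon_offset, s$variable_position)
  })
  ref <- NULL
  if (!is.null(cfg$reference_fasta)) {
    ref_path <- cfg$reference_fasta
    if (!file.exists(ref_path)) {
      ref_path <- file.path(dirname(path), cfg$reference_fasta)
    }
    if (!file.exists(ref_path)) {
      stop("configuration error: reference_fasta not found: ",
           cfg$reference_fasta, call. = FALSE)
    }
    set <- Biostrings::readDNAStringSet(ref_path)
    if (length(set) < 1L) {
      stop("configuration error: reference FASTA is empty", call. = FALSE)
    }
    ref <- as.character(set[[1L]])
  }
  assay <- if (!is.null(cfg$assay)) assay_from_config(cfg$assay) else NULL
  gene_model(gene_name = cfg$gene_name %||% "Vssc",
             sites = sites,
             reference_labels = as.character(cfg$reference_labels %||%
                                               character()),
             reference_sequence = ref,
             intron = cfg$intron,
             assay = assay)
}

#' Write a gene model back to a YAML config
#'
#' Inverse of [load_gene_model()]: reloading the written config reproduces an
#' identical model. If the model carries a reference sequence it is written
#' as a FASTA file next to the config.
#'
#' @param model A [gene_model()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  cfg <- list(
    gene_name = model$gene_name,
    reference_labels = as.list(model$reference_labels),
    sites = lapply(unname(model$sites), function(s) {
      s <- unclass(s)
      s[names(site_field_spec)]
    })
  )
  if (!is.null(model$intron)) cfg$intron <- model$intron
  if (!is.null(model$assay)) cfg$assay <- assay_to_config(model$assay)
  if (!is.null(model$reference_sequence)) {
    fasta <- paste0(tools::file_path_sans_ext(basename(path)), ".fasta")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(model$reference_sequence,
                                               model$gene_name)),
      file.path(dirname(path), fasta))
    cfg$reference_fasta <- fasta
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' The packaged VSSC gene model
#'
#' Loads the default four-site model (M918T, T929I, L1014F, L1014H) with the
#' packaged synthetic reference sequence and PASA assay definition. The model
#' is cached for the session.
#'
#' @return A [gene_model()] with four sites.
#' @export
default_gene_model <- function() {
  if (is.null(.pkg_env$default_model)) {
    cfg <- system.file("extdata", "vssc_gene_model.yaml",
                       package = "kdrscreen", mustWork = TRUE)
    .pkg_env$default_model <- load_gene_model(cfg)
  }
  .pkg_env$default_model
}

#' Translate a codon, expanding IUPAC ambiguity codes
#'
#' Expands every ambiguity code in the codon and translates each expansion
#' under the standard genetic code, returning the set of amino acids. A
#' heterozygous consensus codon such as `YTT` (Y = C/T) therefore returns
#' both `L` and `F` — the logic behind calling RS insects at L1014F.
#'
#' @param codon A 3-character nucleotide string, possibly with IUPAC codes.
#' @return Sorted character vector of one-letter amino acids (`*` = stop).
#' @examples
#' translate_codon("CTT")  # "L"
#' translate_codon("YTT")  # "F" "L"
#' @export
translate_codon <- function(codon) {
  codon <- clean_sequence(codon, "codon")
  if (nchar(codon) != 3L) stop("codon must have length 3", call. = FALSE)
  bases <- lapply(seq_chars(codon), expand_base)
  combos <- expand.grid(bases, stringsAsFactors = FALSE)
  codons <- apply(combos, 1L, paste, collapse = "")
  sort(unique(unname(Biostrings::GENETIC_CODE[codons])))
}

#' Human-readable label for a genotype call at a site
#'
#' @param site A [mutation_site()].
#' @param genotype One of `"SS"`, `"RS"`, `"RR"`.
#' @return A string such as `"L1014F hom-resistant"`, `"T929I het"` or
#'   `"L1014 wild-type"`.
#' @export
mutation_call_label <- function(site, genotype) {
  if (!genotype %in% GENOTYPES) {
    stop("genotype must be one of ", paste(GENOTYPES, collapse = ", "),
         call. = FALSE)
  }
  switch(genotype,
         RR = paste0(site$name, " hom-resistant"),
         RS = paste0(site$name, " het"),
         SS = paste0(site$wild_aa, site$codon_number, " wild-type"))
}
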