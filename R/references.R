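REF_CLASSES <- c("miRNA", "rRNA", "cyto_tRNA", "pre_tRNA", "piRNA_cluster",
                 "mito_tRNA", "lncRNA", "snRNA", "snoRNA", "mRNA",
                 "other_ncRNA", "genome")

# reference class -> small RNA class label used in read-level reporting
REF_TO_SRNA_CLASS <- c(
  miRNA = "miRNA", rRNA = "rsRNA", cyto_tRNA = "tsRNA",
  pre_tRNA = "pre_tsRNA", piRNA_cluster = "piRNA", mito_tRNA = "mt_tsRNA",
  lncRNA = "lncsRNA", snRNA = "snsRNA", snoRNA = "snosRNA",
  mRNA = "mRNA_sRNA", other_ncRNA = "other", genome = "genome")

#' Build mature tRNA references
#'
#' Genomic tRNA sequences lack the post-transcriptionally added 3' CCA tail,
#' and histidine tRNAs carry an extra templated-by-enzyme 5' G (G-1). Mature
#' references therefore get `CCA` suffixed unconditionally, and histidine
#' tRNAs additionally a `G` prefix with the anticodon span shifted by +1.
#'
#' @param raw tibble with columns `ref_id`, `sequence`, `anticodon_start`,
#'   `anticodon_end` (1-based inclusive on the raw sequence), `is_histidine`,
#'   and optionally `isodecoder`.
#' @param class reference class label for the output (default `cyto_tRNA`).
#' @return Tibble of reference records with adjusted sequences and spans.
#' @export
build_mature_trna_refs <- function(raw, class = "cyto_tRNA") {
  if (nrow(raw) == 0) {
    return(tibble::tibble(ref_id = character(0), class = character(0),
                          sequence = character(0),
                          anticodon_start = integer(0),
                          anticodon_end = integer(0),
                          is_histidine = logical(0),
                          isodecoder = character(0)))
  }
  stopifnot(all(c("ref_id", "sequence", "anticodon_start", "anticodon_end",
                  "is_histidine") %in% names(raw)),
            all(raw$anticodon_start >= 1),
            all(raw$anticodon_end <= nchar(raw$sequence)))
  his <- raw$is_histidine
  tibble::tibble(
    ref_id = raw$ref_id,
    class = class,
    sequence = paste0(ifelse(his, "G", ""), raw$sequence, "CCA"),
    anticodon_start = as.integer(raw$anticodon_start + his),
    anticodon_end = as.integer(raw$anticodon_end + his),
    is_histidine = his,
    isodecoder = if ("isodecoder" %in% names(raw)) raw$isodecoder
                 else NA_character_)
}

#' Build tRNA precursor references
#'
#' Each precursor is the genomic slice from 100 bp upstream to 100 bp
#' downstream of a tRNA locus, clipped at contig edges. The mature interval
#' is recorded (1-based on the precursor) so fragment typing can distinguish
#' 5' leader from 3' trailer fragments.
#'
#' @param genome named character vector of contig sequences.
#' @param loci tibble with `ref_id`, `contig`, `start`, `end` (1-based
#'   inclusive on the contig).
#' @param flank flank width in bp (default 100).
#' @return Tibble of `pre_tRNA` reference records with `mature_start`,
#'   `mature_end` columns.
#' @export
build_precursor_refs <- function(genome, loci, flank = 100L) {
  if (nrow(loci) == 0) {
    return(tibble::tibble(ref_id = character(0), class = character(0),
                          sequence = character(0),
                          mature_start = integer(0), mature_end = integer(0)))
  }
  missing_contig <- setdiff(unique(loci$contig), names(genome))
  if (length(missing_contig)) {
    stop("locus on missing contig: ", paste(missing_contig, collapse = ", "),
         call. = FALSE)
  }
  clen <- nchar(genome)[match(loci$contig, names(genome))]
  stopifnot(all(loci$start >= 1), all(loci$end <= clen))
  from <- pmax(1L, loci$start - flank)
  to <- pmin(clen, loci$end + flank)
  tibble::tibble(
    ref_id = paste0(loci$ref_id, "_pre"),
    class = "pre_tRNA",
    sequence = unname(substr(genome[loci$contig], from, to)),
    mature_start = as.integer(loci$start - from + 1L),
    mature_end = as.integer(loci$end - from + 1L))
}

# Normalize heterogeneous reference tibbles to one schema.
as_reference_tbl <- function(...) {
  pieces <- list(...)
  cols <- c("ref_id", "class", "sequence", "anticodon_start",
            "anticodon_end", "is_histidine", "isodecoder",
            "mature_start", "mature_end")
  fill <- list(anticodon_start = NA_integer_, anticodon_end = NA_integer_,
               is_histidine = NA, isodecoder = NA_character_,
               mature_start = NA_integer_, mature_end = NA_integer_)
  out <- purrr::map(pieces, function(p) {
    for (nm in names(fill)) if (!nm %in% names(p)) p[[nm]] <- fill[[nm]]
    p[, cols]
  })
  dplyr::bind_rows(out)
}

#' Assemble an ordered reference database for the annotation cascade
#'
#' @param references tibble of reference records (see
#'   [build_mature_trna_refs()] for the schema; `anticodon_*`, `is_histidine`,
#'   `isodecoder`, `mature_*` may be `NA` for non-tRNA classes).
#' @param stage_order character vector of reference classes in cascade
#'   priority order. The default follows the sequential mapping convention
#'   miRNA, rRNA, cytosolic tRNA, tRNA precursor, piRNA cluster, then the
#'   remaining ncRNA classes, then genome.
#' @return An object of class `cpa_refdb`.
#' @export
reference_db <- function(references,
                         stage_order = c("miRNA", "rRNA", "cyto_tRNA",
                                         "pre_tRNA", "piRNA_cluster",
                                         "mito_tRNA", "lncRNA", "snRNA",
                                         "snoRNA", "mRNA", "other_ncRNA",
                                         "genome")) {
  bad <- setdiff(unique(references$class), REF_CLASSES)
  if (length(bad)) {
    stop("unknown reference class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  refs <- references
  refs$ref_order <- seq_len(nrow(refs))
  structure(list(references = refs,
                 stage_order = intersect(stage_order, unique(refs$class))),
            class = "cpa_refdb")
}

#' @export
print.cpa_refdb <- function(x, ...) {
  cat("<reference db>", nrow(x$references), "references,",
      length(x$stage_order), "stages:",
      paste(x$stage_order, collapse = " > "), "\n")
  invisible(x)
}
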