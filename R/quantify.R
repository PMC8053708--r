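#' Assemble a long-format expression table across libraries
#'
#' Rows are annotated unique sequences; the value columns are the molecule
#' count (`unique_count`), reads-per-million (`rpm`) and the miRNA-anchored
#' normalization (`mirna_norm`).
#'
#' @param hits_by_library named list of annotation hit tibbles (one per
#'   library; see [annotate_cascade()]), each with `sequence`,
#'   `unique_count`, `class`, `srna_class`, `ref_id`, `tsrna_type`.
#' @param include_genome should genome-stage-only reads enter the table
#'   (they always count toward the RPM denominator)?
#' @return A tibble with one row per (sequence, library).
#' @export
expression_table <- function(hits_by_library, include_genome = TRUE) {
  stopifnot(length(hits_by_library) > 0, !is.null(names(hits_by_library)))
  tbl <- dplyr::bind_rows(hits_by_library, .id = "library")
  tbl <- compute_rpm(tbl)
  tbl <- normalize_to_mirna(tbl)
  if (!include_genome) tbl <- tbl[tbl$class != "genome", , drop = FALSE]
  tbl
}

#' Reads-per-million normalization
#'
#' `rpm = unique_count / sum(mapped unique_count) * 1e6` per library. The
#' denominator is all cascade-annotated reads, including the genome stage.
#'
#' @param tbl long expression tibble with `library` and `unique_count`.
#' @return `tbl` with an `rpm` column.
#' @export
compute_rpm <- function(tbl) {
  totals <- tapply(tbl$unique_count, tbl$library, sum)
  if (any(is.na(totals)) || any(totals <= 0)) {
    stop("zero mapped reads in a library", call. = FALSE)
  }
  tbl$rpm <- tbl$unique_count / as.numeric(totals[tbl$library]) * 1e6
  tbl
}

#' miRNA-anchored normalization
#'
#' miRNAs show low terminus multiplicity, so their totals should agree
#' across enzyme treatments; scaling every library so that its summed miRNA
#' RPM equals one million makes non-miRNA abundances comparable between
#' treatment groups. Values stay RPM-like ("miRNA-million" scale).
#'
#' @param tbl long expression tibble with `library`, `srna_class`, `rpm`.
#' @return `tbl` with a `mirna_norm` column.
#' @export
normalize_to_mirna <- function(tbl) {
  mir <- tbl[tbl$srna_class == "miRNA", , drop = FALSE]
  mir_tot <- tapply(mir$rpm, mir$library, sum)
  libs <- unique(tbl$library)
  if (!all(libs %in% names(mir_tot)) || any(mir_tot <= 0)) {
    stop("no miRNA detected in a library", call. = FALSE)
  }
  tbl$mirna_norm <- tbl$rpm * 1e6 / as.numeric(mir_tot[tbl$library])
  tbl
}

#' Per-reference coverage and terminus-end profile
#'
#' Position-wise sum of read abundances over one reference, with separate
#' histograms of read 5' and 3' ends, the read-level view used to display
#' where treatment-responsive fragments sit on their parent RNA.
#'
#' @param hits annotation hits on a single reference (`sequence`, `start`
#'   0-based, and an abundance column).
#' @param ref_length reference length (nt).
#' @param abundance name of the abundance column (default `unique_count`).
#' @param min_display drop reads below this abundance before profiling
#'   (display filter; `0` keeps everything).
#' @return A `cpa_coverage` tibble: `position` (1-based), `coverage`,
#'   `end5`, `end3`.
#' @export
coverage_profile <- function(hits, ref_length, abundance = "unique_count",
                             min_display = 0) {
  stopifnot(length(unique(hits$ref_id)) <= 1)
  w <- hits[[abundance]]
  hits <- hits[w >= min_display, , drop = FALSE]
  w <- w[w >= min_display]
  cov <- numeric(ref_length)
  e5 <- numeric(ref_length)
  e3 <- numeric(ref_length)
  if (nrow(hits)) {
    s <- hits$start + 1L
    e <- hits$start + nchar(hits$sequence)
    stopifnot(all(e <= ref_length))
    for (i in seq_len(nrow(hits))) {
      cov[s[i]:e[i]] <- cov[s[i]:e[i]] + w[i]
    }
    e5_t <- tapply(w, factor(s, levels = seq_len(ref_length)), sum)
    e3_t <- tapply(w, factor(e, levels = seq_len(ref_length)), sum)
    e5 <- ifelse(is.na(e5_t), 0, e5_t)
    e3 <- ifelse(is.na(e3_t), 0, e3_t)
  }
  out <- tibble::tibble(position = seq_len(ref_length), coverage = cov,
                        end5 = as.numeric(e5), end3 = as.numeric(e3))
  class(out) <- c("cpa_coverage", class(out))
  out
}

#' Class composition of a library
#'
#' @param tbl long expression tibble.
#' @param library library label to summarize.
#' @param value abundance column to aggregate (default `unique_count`).
#' @param include_genome keep genome-stage reads in the denominator?
#' @return A `cpa_composition` tibble: `srna_class`, `abundance`,
#'   `fraction` (summing to 1).
#' @export
class_composition <- function(tbl, library, value = "unique_count",
                              include_genome = FALSE) {
  stopifnot(library %in% tbl$library)
  sub <- tbl[tbl$library == library, , drop = FALSE]
  if (!include_genome) sub <- sub[sub$srna_class != "genome", , drop = FALSE]
  out <- sub |>
    dplyr::summarise(abundance = sum(.data[[value]]),
                     .by = "srna_class") |>
    dplyr::mutate(fraction = .data$abundance / sum(.data$abundance)) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
  class(out) <- c("cpa_composition", class(out))
  out
}

#' Greedy parental-sequence grouping
#'
#' Iteratively takes the highest-count unassigned sequence as the parental
#' (representative) sequence and assigns to its group every unassigned
#' sequence related to it by substring containment (member contained in the
#' representative, or containing it); repeats on the residue until all
#' sequences are grouped. Count ties break lexicographically.
#'
#' @param collapsed tibble with `sequence` and a count column.
#' @param count name of the count column (default `unique_count`).
#' @return Tibble (`sequence`, `representative`, `group`) partitioning the
#'   input; `group` numbers follow extraction order.
#' @export
greedy_parent_grouping <- function(collapsed, count = "unique_count") {
  n <- nrow(collapsed)
  if (n == 0) {
    return(tibble::tibble(sequence = character(0),
                          representative = character(0), group = integer(0)))
  }
  ord <- order(-collapsed[[count]], collapsed$sequence)
  seqs <- collapsed$sequence[ord]
  rep_of <- rep(NA_character_, n)
  grp <- rep(NA_integer_, n)
  unassigned <- seq_len(n)
  g <- 0L
  while (length(unassigned)) {
    g <- g + 1L
    head_i <- unassigned[1L]
    rep_seq <- seqs[head_i]
    rest <- unassigned
    members <- rest[stringi::stri_detect_fixed(seqs[rest], rep_seq) |
                      stringi::stri_detect_fixed(rep_seq, seqs[rest])]
    rep_of[members] <- rep_seq
    grp[members] <- g
    unassigned <- setdiff(unassigned, members)
  }
  tibble::tibble(sequence = seqs, representative = rep_of, group = grp)
}
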