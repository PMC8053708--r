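#' Build per-position mismatch pileups from annotation hits
#'
#' Accumulates, for every covered reference position, the read-abundance
#' depth and the mismatch counts by substituted base. Only the cascade's
#' <= 1-mismatch alignments contribute, so a methylated read carrying an
#' additional sequencing error is lost — a small, documented downward bias.
#'
#' @param hits annotation hits (`sequence`, `ref_id`, `start` 0-based,
#'   abundance column).
#' @param refs reference tibble (`ref_id`, `sequence`).
#' @param abundance abundance column name (default `unique_count`).
#' @return A `cpa_pileup` tibble: `ref_id`, `position` (1-based),
#'   `ref_base`, `depth`, `n_mismatch`, and per-base mismatch counts
#'   `mm_A`, `mm_C`, `mm_G`, `mm_T`.
#' @export
build_pileup <- function(hits, refs, abundance = "unique_count") {
  empty <- tibble::tibble(ref_id = character(0), position = integer(0),
                          ref_base = character(0), depth = numeric(0),
                          n_mismatch = numeric(0), mm_A = numeric(0),
                          mm_C = numeric(0), mm_G = numeric(0),
                          mm_T = numeric(0))
  if (nrow(hits) == 0) {
    class(empty) <- c("cpa_pileup", class(empty))
    return(empty)
  }
  ridx <- match(hits$ref_id, refs$ref_id)
  if (anyNA(ridx)) stop("hit on unknown reference", call. = FALSE)
  L <- nchar(hits$sequence)
  if (any(hits$start + L > nchar(refs$sequence[ridx]))) {
    stop("hit inconsistent with reference length", call. = FALSE)
  }
  w <- hits[[abundance]]
  # expand hits to (ref, position, read_base, ref_base, weight)
  per <- rep.int(seq_len(nrow(hits)), L)
  off <- sequence(L) # 1..L within each hit
  pos <- hits$start[per] + off
  read_base <- stringi::stri_sub(hits$sequence[per], off, length = 1)
  ref_base <- stringi::stri_sub(refs$sequence[ridx[per]], pos, length = 1)
  tb <- tibble::tibble(ref_id = hits$ref_id[per], position = pos,
                       ref_base = ref_base, read_base = read_base,
                       weight = w[per])
  out <- tb |>
    dplyr::summarise(
      depth = sum(.data$weight),
      n_mismatch = sum(.data$weight[.data$read_base != .data$ref_base]),
      mm_A = sum(.data$weight[.data$read_base == "A" &
                                .data$ref_base != "A"]),
      mm_C = sum(.data$weight[.data$read_base == "C" &
                                .data$ref_base != "C"]),
      mm_G = sum(.data$weight[.data$read_base == "G" &
                                .data$ref_base != "G"]),
      mm_T = sum(.data$weight[.data$read_base == "T" &
                                .data$ref_base != "T"]),
      .by = c("ref_id", "position", "ref_base")) |>
    dplyr::arrange(.data$ref_id, .data$position)
  class(out) <- c("cpa_pileup", class(out))
  out
}

#' Call methylated sites from paired pileups
#'
#' Compares the mismatch frequency without AlkB demethylation against the
#' frequency with it: a genuine m1A/m3C/m1G site misincorporates frequently
#' in the untreated library and loses that signal after demethylation. A
#' site is called iff the reference base is A, C or G, depth reaches
#' `depth_min` in both groups, the no-AlkB mismatch frequency reaches
#' `f_min`, and demethylation reduces it at least `reduction_min`-fold.
#' The kind follows the reference base (A -> m1A, C -> m3C, G -> m1G).
#'
#' @param pileup_noAlkB,pileup_withAlkB [build_pileup()] results for the
#'   library pair (e.g. CP vs CPA).
#' @param f_min minimum no-AlkB mismatch frequency (default 0.10).
#' @param depth_min minimum depth in both groups (default 50).
#' @param reduction_min minimum fold reduction of the mismatch frequency
#'   after AlkB (default 3).
#' @return A `cpa_methyl_calls` tibble: `ref_id`, `position`, `ref_base`,
#'   `kind`, `f_noAlkB`, `f_withAlkB`, `depth_noAlkB`, `depth_withAlkB`,
#'   `delta`, `stoichiometry_estimate`.
#' @export
call_methylation_sites <- function(pileup_noAlkB, pileup_withAlkB,
                                   f_min = 0.10, depth_min = 50,
                                   reduction_min = 3) {
  joined <- dplyr::inner_join(
    pileup_noAlkB[, c("ref_id", "position", "ref_base", "depth",
                      "n_mismatch")],
    pileup_withAlkB[, c("ref_id", "position", "depth", "n_mismatch")],
    by = c("ref_id", "position"), suffix = c("_no", "_with"))
  joined$f_noAlkB <- joined$n_mismatch_no / joined$depth_no
  joined$f_withAlkB <- joined$n_mismatch_with / joined$depth_with
  ok <- joined$ref_base %in% c("A", "C", "G") &
    joined$depth_no >= depth_min & joined$depth_with >= depth_min &
    joined$f_noAlkB >= f_min &
    joined$f_noAlkB / joined$f_withAlkB >= reduction_min
  ok[is.na(ok)] <- FALSE # 0/0 frequency ratios are never calls
  calls <- joined[ok, , drop = FALSE]
  kinds <- stats::setNames(names(METHYL_KINDS), METHYL_KINDS)
  out <- tibble::tibble(
    ref_id = calls$ref_id, position = calls$position,
    ref_base = calls$ref_base,
    kind = unname(kinds[calls$ref_base]),
    f_noAlkB = calls$f_noAlkB, f_withAlkB = calls$f_withAlkB,
    depth_noAlkB = calls$depth_no, depth_withAlkB = calls$depth_with)
  out <- estimate_stoichiometry(out)
  class(out) <- c("cpa_methyl_calls", class(out))
  out
}

#' Stoichiometry estimate for methylation calls
#'
#' Reported as the mismatch-frequency difference
#' `delta = f_noAlkB - f_withAlkB`. This is a misincorporation-rate
#' confounded lower bound: under the simulator's generative model with stop
#' rate 0, its expectation is `stoichiometry * misinc_rate`, so a known
#' misincorporation rate can be divided out.
#'
#' @param calls tibble with `f_noAlkB` and `f_withAlkB` columns.
#' @return `calls` with `delta` and `stoichiometry_estimate` columns.
#' @export
estimate_stoichiometry <- function(calls) {
  calls$delta <- calls$f_noAlkB - calls$f_withAlkB
  calls$stoichiometry_estimate <- calls$delta
  calls
}
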