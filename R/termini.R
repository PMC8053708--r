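OMITTED_TO_CHEMISTRY <- c(pnk = "pnk_responsive",
                          cap_clip = "capclip_responsive",
                          alkb = "alkb_responsive")

#' Call treatment-responsive sequences
#'
#' The core differential-detection inference: a sequence abundant in the
#' fully treated library but depleted in a library lacking one enzyme must
#' carry the chemistry that enzyme converts. With pseudocount `eps`,
#' `fold_change = (full + eps) / (reduced + eps)`; a sequence is responsive
#' iff `full >= min_full` and `fold_change > fc_threshold`. The chemistry
#' label is a pure function of the omitted enzyme:
#' `pnk` -> 5'-OH or 3'-P/3'-cP, `cap_clip` -> 5'-cap or 5'-ppp,
#' `alkb` -> m1A/m3C/m1G.
#'
#' @param full_tbl,reduced_tbl expression tibbles for the full and the
#'   enzyme-omitted library (columns `sequence`, `srna_class`, and the value
#'   layer; replicates should be averaged upstream).
#' @param omitted_enzyme one of `"pnk"`, `"cap_clip"`, `"alkb"`.
#' @param fc_threshold fold-change cut (default 30).
#' @param min_full minimum full-library abundance (shot-noise guard).
#' @param eps pseudocount.
#' @param value value column, default the miRNA-anchored layer
#'   (`mirna_norm`), which is introduced precisely to make treatment groups
#'   comparable.
#' @return A `cpa_responsive` tibble of responsive sequences: `sequence`,
#'   `srna_class`, `full_value`, `reduced_value`, `fold_change`,
#'   `inferred_chemistry`.
#' @export
call_responsive <- function(full_tbl, reduced_tbl, omitted_enzyme,
                            fc_threshold = 30, min_full = 10, eps = 0.5,
                            value = "mirna_norm") {
  if (!omitted_enzyme %in% names(OMITTED_TO_CHEMISTRY)) {
    stop("unknown omitted enzyme: ", omitted_enzyme, call. = FALSE)
  }
  if (!value %in% names(full_tbl) || !value %in% names(reduced_tbl)) {
    stop("value layer `", value, "` missing from a table", call. = FALSE)
  }
  key <- intersect(intersect(names(full_tbl), names(reduced_tbl)),
                   c("sequence", "srna_class", "class", "ref_id",
                     "tsrna_type"))
  take <- function(tbl, nm) {
    out <- tbl[, c(key, value)]
    names(out)[names(out) == value] <- nm
    out
  }
  joined <- dplyr::full_join(take(full_tbl, "full_value"),
                             take(reduced_tbl, "reduced_value"),
                             by = key)
  joined$full_value[is.na(joined$full_value)] <- 0
  joined$reduced_value[is.na(joined$reduced_value)] <- 0
  joined$fold_change <- (joined$full_value + eps) /
    (joined$reduced_value + eps)
  out <- joined[joined$full_value >= min_full &
                  joined$fold_change > fc_threshold, , drop = FALSE]
  out$inferred_chemistry <- unname(OMITTED_TO_CHEMISTRY[omitted_enzyme])
  class(out) <- c("cpa_responsive", class(out))
  out
}

#' Class composition of responsive calls
#'
#' @param calls a [call_responsive()] result.
#' @param value column to weight by (default `full_value`).
#' @return A `cpa_composition` tibble (`srna_class`, `abundance`,
#'   `fraction`); fractions sum to 1.
#' @export
responsive_composition <- function(calls, value = "full_value") {
  out <- calls |>
    dplyr::summarise(abundance = sum(.data[[value]]), .by = "srna_class") |>
    dplyr::mutate(fraction = .data$abundance / sum(.data$abundance)) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
  class(out) <- c("cpa_composition", class(out))
  out
}
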