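#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-species result
#'
#' @param x a `cpa_diff` object ([differential_species()]).
#' @param ... unused.
#' @return A tibble with one row per tested sequence.
#' @export
tidy.cpa_diff <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a differential-species result
#'
#' @param x a `cpa_diff` object.
#' @param ... unused.
#' @return A one-row tibble: sequences tested, selected, and per direction.
#' @export
glance.cpa_diff <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x),
                 n_selected = sum(x$selected),
                 n_up_a = sum(x$selected & x$direction == "A>B"),
                 n_up_b = sum(x$selected & x$direction == "B>A"))
}

#' Tidy per-class clustering trees
#'
#' @param x a `cpa_clust` object ([cluster_by_class()]).
#' @param ... unused.
#' @return A tibble of merge steps per class: `srna_class`, `step`,
#'   `height`, and the two merged nodes in `stats::hclust` convention
#'   (negative = singleton row, positive = earlier merge).
#' @export
tidy.cpa_clust <- function(x, ...) {
  purrr::imap(x$trees, function(t, cls) {
    if (is.null(t$tree)) {
      return(tibble::tibble(srna_class = cls, step = integer(0),
                            height = numeric(0), node1 = integer(0),
                            node2 = integer(0)))
    }
    h <- t$tree
    tibble::tibble(srna_class = cls, step = seq_len(nrow(h$merge)),
                   height = h$height, node1 = h$merge[, 1],
                   node2 = h$merge[, 2])
  }) |>
    dplyr::bind_rows()
}

#' One-row-per-class summary of per-class clustering
#'
#' @param x a `cpa_clust` object.
#' @param ... unused.
#' @return A tibble: class, number of sequences, maximum merge height.
#' @export
glance.cpa_clust <- function(x, ...) {
  purrr::imap(x$trees, function(t, cls) {
    tibble::tibble(srna_class = cls, n_sequences = length(t$ids),
                   max_height = if (is.null(t$tree)) NA_real_
                                else max(t$tree$height))
  }) |>
    dplyr::bind_rows()
}

#' Tidy a TSI table
#'
#' @param x a `cpa_tsi` object.
#' @param ... unused.
#' @return The underlying tibble.
#' @export
tidy.cpa_tsi <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a TSI table
#'
#' @param x a `cpa_tsi` object.
#' @param ... unused.
#' @return A one-row tibble: sequences scored, median TSI, and the number
#'   of single-tissue (TSI = 1) rows.
#' @export
glance.cpa_tsi <- function(x, ...) {
  tibble::tibble(n = nrow(x), median_tsi = stats::median(x$tsi),
                 n_single_tissue = sum(x$tsi >= 1))
}
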