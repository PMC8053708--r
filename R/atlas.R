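#' Tissue specificity index
#'
#' `TSI = (N - sum(x) / max(x)) / (N - 1)` for a nonnegative expression
#' vector over `N >= 2` tissues: 1 when expressed in a single tissue, 0 when
#' perfectly uniform, and invariant to scaling of the row.
#'
#' @param x nonnegative numeric vector of per-tissue expression.
#' @return TSI in \[0, 1\].
#' @examples
#' compute_tsi(c(80, 0, 0, 0, 0, 0, 0, 0, 0)) # 1
#' compute_tsi(c(80, 10, 10, 0, 0, 0, 0, 0, 0)) # 0.96875
#' @export
compute_tsi <- function(x) {
  n <- length(x)
  stopifnot(n >= 2, all(x >= 0))
  m <- max(x)
  if (m <= 0) stop("all-zero expression row", call. = FALSE)
  (n - sum(x) / m) / (n - 1)
}

#' Per-sequence TSI over a tissue expression table
#'
#' @param tbl long tibble with columns `sequence` (or another id), a tissue
#'   column and a value column; or a wide matrix-like data frame via
#'   [tsi_from_matrix()].
#' @param id,tissue,value column names.
#' @return A `cpa_tsi` tibble: id column, `tsi`, `max_tissue`, `max_value`,
#'   plus any per-id constant annotation columns (e.g. `srna_class`).
#' @export
tissue_specificity <- function(tbl, id = "sequence", tissue = "library",
                               value = "rpm") {
  wide <- tbl |>
    dplyr::summarise(value = sum(.data[[value]]),
                     .by = dplyr::all_of(c(id, tissue))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(tissue),
                       values_from = "value", values_fill = 0)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  stopifnot(ncol(mat) >= 2)
  keep <- rowSums(mat) > 0
  wide <- wide[keep, , drop = FALSE]
  mat <- mat[keep, , drop = FALSE]
  out <- tibble::tibble(
    !!id := wide[[id]],
    tsi = apply(mat, 1, compute_tsi),
    max_tissue = colnames(mat)[max.col(mat, ties.method = "first")],
    max_value = apply(mat, 1, max))
  anno <- tbl |>
    dplyr::select(dplyr::all_of(id),
                  dplyr::any_of(c("srna_class", "class", "ref_id",
                                  "tsrna_type"))) |>
    dplyr::distinct(.data[[id]], .keep_all = TRUE)
  out <- dplyr::left_join(out, anno, by = id)
  class(out) <- c("cpa_tsi", class(out))
  out
}

DEFAULT_CLASS_RPM_MIN <- c(mt_tsRNA = 70, lncsRNA = 50, snsRNA = 50,
                           snosRNA = 30, default = 20)

#' Filter for tissue-enriched small RNAs
#'
#' Keeps rows passing a class-specific expression floor (maximum value over
#' tissues above the class threshold) and a TSI cut. Default floors follow
#' the atlas convention: mitochondrial tsRNAs 70, lncsRNAs 50, snsRNAs 50,
#' snosRNAs 30, everything else 20 RPM, with TSI > 0.95; unknown classes
#' fall back to the default floor.
#'
#' @param tsi_tbl a [tissue_specificity()] result (needs `tsi`,
#'   `max_value`, `max_tissue` and a class column).
#' @param class_thresholds named vector of per-class RPM floors, with a
#'   `default` entry.
#' @param tsi_min TSI threshold (exclusive).
#' @param class_col class column name.
#' @return The enriched subset, with an `rpm_floor` column recording the
#'   threshold applied.
#' @export
filter_and_enrich <- function(tsi_tbl,
                              class_thresholds = DEFAULT_CLASS_RPM_MIN,
                              tsi_min = 0.95, class_col = "srna_class") {
  stopifnot("default" %in% names(class_thresholds))
  cls <- tsi_tbl[[class_col]]
  floor_v <- class_thresholds[cls]
  floor_v[is.na(floor_v)] <- class_thresholds[["default"]]
  keep <- tsi_tbl$max_value > floor_v & tsi_tbl$tsi > tsi_min
  out <- tsi_tbl[keep, , drop = FALSE]
  out$rpm_floor <- unname(floor_v[keep])
  out
}

#' Per-class hierarchical clustering of tissue expression
#'
#' Rows are prefiltered to those expressed above `min_rpm` in at least one
#' tissue, split by small-RNA class, log2(x + 1) transformed, and clustered
#' by average-linkage agglomeration on Euclidean distances. Output is
#' deterministic for a fixed input.
#'
#' @param tbl long expression tibble (`sequence`, class column, tissue
#'   column, value column).
#' @param min_rpm expression prefilter (default 20, in at least one tissue).
#' @param id,tissue,value,class_col column names.
#' @return A `cpa_clust` object: named list of `hclust` trees (classes with
#'   a single row yield `NULL` with the row recorded), plus the filtered
#'   matrix rows per class.
#' @export
cluster_by_class <- function(tbl, min_rpm = 20, id = "sequence",
                             tissue = "library", value = "rpm",
                             class_col = "srna_class") {
  wide <- tbl |>
    dplyr::summarise(value = sum(.data[[value]]),
                     .by = dplyr::all_of(c(id, class_col, tissue))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(tissue),
                       values_from = "value", values_fill = 0)
  mat <- as.matrix(wide[, -(1:2), drop = FALSE])
  keep <- apply(mat, 1, max) > min_rpm
  wide <- wide[keep, , drop = FALSE]
  mat <- log2(mat[keep, , drop = FALSE] + 1)
  rownames(mat) <- wide[[id]]
  split_rows <- split(seq_len(nrow(mat)), wide[[class_col]])
  trees <- purrr::map(split_rows, function(rows) {
    sub <- mat[rows, , drop = FALSE]
    # deterministic input order: sort rows by id before clustering
    sub <- sub[order(rownames(sub)), , drop = FALSE]
    if (nrow(sub) < 2) {
      return(list(tree = NULL, ids = rownames(sub)))
    }
    list(tree = stats::hclust(stats::dist(sub, method = "euclidean"),
                              method = "average"),
         ids = rownames(sub))
  })
  structure(list(trees = trees, matrix = mat,
                 classes = wide[[class_col]]),
            class = "cpa_clust")
}

#' @export
print.cpa_clust <- function(x, ...) {
  cat("<per-class clustering>", length(x$trees), "classes,",
      nrow(x$matrix), "sequences\n")
  invisible(x)
}

#' Differentially detected small RNAs between two groups
#'
#' Two-sided Welch t-test on log2(value + 1) over replicates, with a linear
#' mean fold-change gate: selected iff `P < p_max` and the mean fold change
#' (larger group over smaller, pseudocount `eps`) exceeds `fc_min`.
#'
#' @param group_a,group_b tibbles of replicate expression (`sequence`,
#'   replicate column, value column); >= 2 replicates each.
#' @param p_max,fc_min selection thresholds (defaults 0.05 and 2).
#' @param value value column (default `rpm`).
#' @param eps pseudocount for the fold change.
#' @return A `cpa_diff` tibble: `sequence`, `mean_a`, `mean_b`,
#'   `fold_change`, `direction`, `p_value`, `selected`.
#' @export
differential_species <- function(group_a, group_b, p_max = 0.05, fc_min = 2,
                                 value = "rpm", eps = 0.5) {
  spread <- function(tbl) {
    split(tbl[[value]], tbl$sequence)
  }
  xa <- spread(group_a)
  xb <- spread(group_b)
  if (any(lengths(xa) < 2) || any(lengths(xb) < 2)) {
    stop("need >= 2 replicates per group", call. = FALSE)
  }
  seqs <- union(names(xa), names(xb))
  n_a <- max(lengths(xa))
  n_b <- max(lengths(xb))
  res <- purrr::map(seqs, function(s) {
    a <- xa[[s]] %||% rep(0, n_a)
    b <- xb[[s]] %||% rep(0, n_b)
    la <- log2(a + 1)
    lb <- log2(b + 1)
    p <- if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
      if (mean(la) == mean(lb)) 1 else 0
    } else {
      stats::t.test(la, lb, var.equal = FALSE)$p.value
    }
    ma <- mean(a)
    mb <- mean(b)
    fc <- (max(ma, mb) + eps) / (min(ma, mb) + eps)
    tibble::tibble(sequence = s, mean_a = ma, mean_b = mb, fold_change = fc,
                   direction = if (ma >= mb) "A>B" else "B>A", p_value = p)
  })
  out <- dplyr::bind_rows(res)
  out$selected <- out$p_value < p_max & out$fold_change > fc_min
  class(out) <- c("cpa_diff", class(out))
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
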