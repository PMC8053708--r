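# All substrings of the given lengths from each reference, as a lookup
# table keyed by sequence. Deduplicated keeping the first hit in
# (ref_order, start) priority, which encodes the cascade tie-break.
substring_index <- function(refs, lengths) {
  lengths <- sort(unique(lengths))
  pieces <- vector("list", length(lengths))
  for (k in seq_along(lengths)) {
    L <- lengths[k]
    ok <- which(nchar(refs$sequence) >= L)
    if (!length(ok)) next
    per <- lapply(ok, function(i) {
      n <- nchar(refs$sequence[i]) - L + 1L
      tibble::tibble(
        key = stringi::stri_sub(refs$sequence[i], seq_len(n),
                                length = L),
        ref_idx = i,
        start = seq_len(n))
    })
    pieces[[k]] <- dplyr::bind_rows(per)
  }
  idx <- dplyr::bind_rows(pieces)
  if (nrow(idx) == 0) return(idx)
  idx <- idx[order(idx$ref_idx, idx$start), ]
  idx[!duplicated(idx$key), ]
}

# Exact lookup of query sequences against a substring index.
# Returns tibble(query_idx, ref_idx, start, mismatches = 0), one row per hit.
exact_hits <- function(queries, idx) {
  if (nrow(idx) == 0 || length(queries) == 0) {
    return(tibble::tibble(query_idx = integer(0), ref_idx = integer(0),
                          start = integer(0), mismatches = integer(0)))
  }
  m <- match(queries, idx$key)
  hit <- which(!is.na(m))
  tibble::tibble(query_idx = hit, ref_idx = idx$ref_idx[m[hit]],
                 start = idx$start[m[hit]],
                 mismatches = 0L)
}

# One-mismatch hits by pigeonhole: split each query in half; with at most
# one mismatch, at least one half must occur exactly, which a half-length
# substring index finds; candidate placements are then verified by Hamming
# distance. Returns the single best hit per query under the tie-break
# (fewest mismatches, then reference order, then leftmost start).
onemm_hits <- function(queries, refs) {
  if (length(queries) == 0) {
    return(tibble::tibble(query_idx = integer(0), ref_idx = integer(0),
                          start = integer(0), mismatches = integer(0)))
  }
  qlen <- nchar(queries)
  h1_len <- qlen %/% 2L
  halves <- tibble::tibble(
    query_idx = rep(seq_along(queries), 2L),
    key = c(substr(queries, 1L, h1_len),
            substr(queries, h1_len + 1L, qlen)),
    offset = c(rep(0L, length(queries)), h1_len))
  idx <- substring_index_multi(refs, unique(nchar(halves$key)))
  cand <- dplyr::inner_join(halves, idx, by = "key",
                            relationship = "many-to-many")
  if (nrow(cand) == 0) {
    return(tibble::tibble(query_idx = integer(0), ref_idx = integer(0),
                          start = integer(0), mismatches = integer(0)))
  }
  cand$start <- cand$start - cand$offset
  cand <- cand[cand$start >= 1L, c("query_idx", "ref_idx", "start")]
  cand <- dplyr::distinct(cand)
  L <- nchar(queries)[cand$query_idx]
  reflen <- nchar(refs$sequence)[cand$ref_idx]
  cand <- cand[cand$start + L - 1L <= reflen, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(query_idx = integer(0), ref_idx = integer(0),
                          start = integer(0), mismatches = integer(0)))
  }
  window <- stringi::stri_sub(refs$sequence[cand$ref_idx], cand$start,
                              length = nchar(queries)[cand$query_idx])
  cand$mismatches <- hamming_pairs(queries[cand$query_idx], window)
  cand <- cand[cand$mismatches <= 1L, , drop = FALSE]
  cand |>
    dplyr::arrange(.data$query_idx, .data$mismatches, .data$ref_idx,
                   .data$start) |>
    dplyr::distinct(.data$query_idx, .keep_all = TRUE)
}

# Unlike substring_index(), keep every occurrence (needed for pigeonhole
# candidate generation, where all placements of a half matter).
substring_index_multi <- function(refs, lengths) {
  lengths <- sort(unique(lengths))
  pieces <- list()
  for (L in lengths) {
    ok <- which(nchar(refs$sequence) >= L)
    for (i in ok) {
      n <- nchar(refs$sequence[i]) - L + 1L
      pieces[[length(pieces) + 1L]] <- tibble::tibble(
        key = stringi::stri_sub(refs$sequence[i], seq_len(n), length = L),
        ref_idx = i, start = seq_len(n))
    }
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) {
    out <- tibble::tibble(key = character(0), ref_idx = integer(0),
                          start = integer(0))
  }
  out
}

# Vectorized sense-strand alignment of queries against a reference set.
# Exact hits win; remaining queries go through the pigeonhole route when
# max_mismatches == 1. Returns one best hit per aligned query.
align_stage <- function(queries, refs, max_mismatches) {
  idx <- substring_index(refs, unique(nchar(queries)))
  ex <- exact_hits(queries, idx)
  out <- ex
  if (max_mismatches >= 1L) {
    rest <- setdiff(seq_along(queries), ex$query_idx)
    if (length(rest)) {
      mm <- onemm_hits(queries[rest], refs)
      mm$query_idx <- rest[mm$query_idx]
      out <- dplyr::bind_rows(ex, mm)
    }
  }
  out
}

#' Align one read against a reference set
#'
#' Sense-strand only (no reverse complement). Exact placements are found
#' through a substring index; one-mismatch placements through a pigeonhole
#' split in which one half of the read must match exactly. When several
#' placements exist the hit is chosen deterministically: fewest mismatches,
#' then earliest reference in input order, then leftmost start.
#'
#' @param seq a single read sequence.
#' @param references tibble with `ref_id` and `sequence` (and optionally
#'   `class`) in priority order.
#' @param max_mismatches 0 or 1.
#' @return A one-row tibble (`ref_id`, `class` if present, `start` 0-based,
#'   `mismatches`), or a zero-row tibble when there is no hit.
#' @export
align_read <- function(seq, references, max_mismatches = 1) {
  stopifnot(length(seq) == 1, max_mismatches %in% c(0L, 1L))
  hit <- align_stage(seq, references, as.integer(max_mismatches))
  if (nrow(hit) == 0) {
    return(tibble::tibble(ref_id = character(0), start = integer(0),
                          mismatches = integer(0)))
  }
  out <- tibble::tibble(ref_id = references$ref_id[hit$ref_idx],
                        start = hit$start - 1L,
                        mismatches = hit$mismatches)
  if ("class" %in% names(references)) {
    out$class <- references$class[hit$ref_idx]
    out <- out[, c("ref_id", "class", "start", "mismatches")]
  }
  out
}

#' Annotate collapsed reads through the ordered reference cascade
#'
#' Each read is tried against the reference classes in cascade order; the
#' first stage with a hit assigns the class. Stage gates follow the
#' sequential small-RNA mapping convention: the miRNA stage accepts only
#' reads of 16-28 nt and allows zero mismatches (so tRNA fragments sharing a
#' miRNA-like sequence fall through rather than being misannotated); the
#' piRNA-cluster stage accepts only 24-32 nt; every other stage allows one
#' mismatch. Reads annotated only at the genome stage are reported with
#' class `genome` and are excluded from class-composition denominators by
#' default downstream.
#'
#' @param collapsed tibble from [dedup_and_collapse()] (needs `sequence`;
#'   other columns carried through).
#' @param db a [reference_db()].
#' @param mirna_len c(min, max) gate for the miRNA stage.
#' @param pirna_len c(min, max) gate for the piRNA stage.
#' @param max_mismatches mismatch allowance for non-miRNA stages (0 or 1).
#' @return A list with `hits` (input columns + `class`, `srna_class`,
#'   `ref_id`, `start` 0-based, `mismatches`, `tsrna_type`) and
#'   `unannotated` (input rows with no hit anywhere).
#' @export
annotate_cascade <- function(collapsed, db, mirna_len = c(16L, 28L),
                             pirna_len = c(24L, 32L), max_mismatches = 1) {
  stopifnot(inherits(db, "cpa_refdb"))
  refs <- db$references
  seqs <- collapsed$sequence
  lens <- nchar(seqs)
  assigned <- rep(NA_integer_, length(seqs)) # row into refs
  start0 <- rep(NA_integer_, length(seqs))
  mism <- rep(NA_integer_, length(seqs))

  remaining <- seq_along(seqs)
  for (stage in db$stage_order) {
    if (!length(remaining)) break
    stage_refs <- refs[refs$class == stage, , drop = FALSE]
    if (nrow(stage_refs) == 0) next
    if (stage == "miRNA") {
      eligible <- remaining[lens[remaining] >= mirna_len[1] &
                              lens[remaining] <= mirna_len[2]]
      mm <- 0L
    } else if (stage == "piRNA_cluster") {
      eligible <- remaining[lens[remaining] >= pirna_len[1] &
                              lens[remaining] <= pirna_len[2]]
      mm <- as.integer(max_mismatches)
    } else {
      eligible <- remaining
      mm <- as.integer(max_mismatches)
    }
    if (!length(eligible)) next
    hits <- align_stage(seqs[eligible], stage_refs, mm)
    if (nrow(hits)) {
      rows <- eligible[hits$query_idx]
      assigned[rows] <- stage_refs$ref_order[hits$ref_idx]
      start0[rows] <- hits$start - 1L
      mism[rows] <- hits$mismatches
      remaining <- setdiff(remaining, rows)
    }
  }

  hit_rows <- which(!is.na(assigned))
  ref_at <- match(assigned[hit_rows], refs$ref_order)
  hits <- collapsed[hit_rows, , drop = FALSE]
  hits$class <- refs$class[ref_at]
  hits$srna_class <- unname(REF_TO_SRNA_CLASS[hits$class])
  hits$ref_id <- refs$ref_id[ref_at]
  hits$start <- start0[hit_rows]
  hits$mismatches <- mism[hit_rows]
  hits$tsrna_type <- classify_tsrna(hits, refs)
  list(hits = hits, unannotated = collapsed[is.na(assigned), , drop = FALSE])
}

#' Type tRNA-derived fragments
#'
#' Concretizes anticodon-anchored fragment typing on mature tRNA
#' references: with the anticodon loop taken as the anticodon span widened
#' by `loop_pad` nt on each side, a fragment starting at the 5' end (within
#' `start_tol` of position 1, tolerating the histidine G-1) is a 5' half if
#' its 3' end falls inside the loop and a tRF-5 if it ends before the loop;
#' a fragment ending at the reference 3' end (within the last `cca_tol` nt,
#' the CCA) is a 3' half if it starts inside the loop and a tRF-3 if it
#' starts after the loop; anything else is internal. On precursor
#' references, overlap with the upstream flank gives `leader5` and with the
#' downstream flank `trailer3`.
#'
#' @param hits tibble with `class`, `ref_id`, `start` (0-based) and
#'   `sequence` columns.
#' @param refs reference tibble carrying `anticodon_start`/`anticodon_end`
#'   (mature tRNA classes) and `mature_start`/`mature_end` (precursors).
#' @param loop_pad,cca_tol,start_tol boundary tolerances (nt).
#' @return Character vector of fragment types (`tRF5`, `half5`, `half3`,
#'   `tRF3`, `internal`, `leader5`, `trailer3`), `NA` for non-tRNA classes.
#' @export
classify_tsrna <- function(hits, refs, loop_pad = 2L, cca_tol = 3L,
                           start_tol = 1L) {
  out <- rep(NA_character_, nrow(hits))
  if (!nrow(hits)) return(out)
  ridx <- match(hits$ref_id, refs$ref_id)
  s1 <- hits$start + 1L # 1-based start
  e1 <- hits$start + nchar(hits$sequence) # 1-based inclusive end
  reflen <- nchar(refs$sequence[ridx])

  mat <- which(hits$class %in% c("cyto_tRNA", "mito_tRNA"))
  if (length(mat)) {
    acs <- refs$anticodon_start[ridx[mat]]
    ace <- refs$anticodon_end[ridx[mat]]
    if (anyNA(acs)) stop("missing anticodon_span on a tRNA reference")
    loop_s <- acs - loop_pad
    loop_e <- ace + loop_pad
    s <- s1[mat]; e <- e1[mat]; L <- reflen[mat]
    at5 <- s <= 1L + start_tol
    at3 <- e >= L - cca_tol + 1L
    type <- rep("internal", length(mat))
    type[at5 & e >= loop_s & e <= loop_e] <- "half5"
    type[at5 & e < loop_s] <- "tRF5"
    type[!at5 & at3 & s >= loop_s & s <= loop_e] <- "half3"
    type[!at5 & at3 & s > loop_e] <- "tRF3"
    out[mat] <- type
  }

  pre <- which(hits$class == "pre_tRNA")
  if (length(pre)) {
    ms <- refs$mature_start[ridx[pre]]
    me <- refs$mature_end[ridx[pre]]
    if (anyNA(ms)) stop("missing mature interval on a precursor reference")
    type <- rep("internal", length(pre))
    type[e1[pre] > me] <- "trailer3"
    type[s1[pre] < ms] <- "leader5" # leader wins if both flanks touched
    out[pre] <- type
  }
  out
}
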