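phred_means <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

# mismatch counts between equal-length string pairs
hamming_pairs <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# Locate the leftmost 3'-adapter occurrence in each read: a full-length
# exact match, or a >= min_overlap adapter prefix at the read end tolerating
# max_mismatch_rate mismatches. Returns 0-based insert length, or NA.
locate_adapter <- function(sequence, adapter3, min_overlap, max_mismatch_rate) {
  pos <- stringi::stri_locate_first_fixed(sequence, adapter3)[, "start"]
  out <- pos - 1L
  miss <- which(is.na(out))
  alen <- nchar(adapter3)
  araw <- charToRaw(adapter3)
  mm_full <- floor(max_mismatch_rate * alen)
  for (i in miss) {
    rl <- nchar(sequence[i])
    best <- NA_integer_
    # mismatch-tolerant full-length occurrence, leftmost first
    if (rl >= alen && mm_full > 0) {
      rraw <- charToRaw(sequence[i])
      for (s in seq_len(rl - alen + 1L)) {
        if (sum(rraw[s:(s + alen - 1L)] != araw) <= mm_full) {
          best <- s - 1L
          break
        }
      }
    }
    if (!is.na(best)) {
      out[i] <- best
      next
    }
    L_hi <- min(alen - 1L, rl)
    if (L_hi < min_overlap) {
      out[i] <- best
      next
    }
    for (L in seq(L_hi, min_overlap)) {
      frag <- substr(sequence[i], rl - L + 1L, rl)
      mm <- sum(charToRaw(frag) != charToRaw(substr(adapter3, 1L, L)))
      if (mm <= floor(max_mismatch_rate * L)) {
        best <- rl - L
        break
      }
    }
    out[i] <- best
  }
  out
}

#' Trim 3' adapters and filter reads
#'
#' Locates the leftmost 3'-adapter occurrence (full match anywhere, or a
#' mismatch-tolerant adapter prefix of at least `min_overlap` nt at the read
#' end) and truncates the read there. Reads with mean Phred below `q_min`
#' are rejected as `low_quality`; trimmed sequences outside
#' `[len_min, len_max]` are rejected as `too_short`/`too_long`. Reads with
#' no adapter hit are kept at full length and so normally fall to the length
#' gate (`too_long`) rather than being discarded outright — short real
#' inserts whose adapter carries sequencing errors remain salvageable via
#' the mismatch-tolerant match.
#'
#' @param reads tibble with `sequence` and `quality` columns (and optionally
#'   `id`).
#' @param adapter3 3' adapter sequence.
#' @param min_overlap minimum adapter prefix length at the read end (>= 3).
#' @param max_mismatch_rate tolerated mismatch fraction in adapter matches.
#' @param q_min minimum mean Phred score.
#' @param len_min,len_max accepted trimmed-sequence length range. The
#'   small-RNA gate is 15-40 nt; when trimming upstream of UMI extraction,
#'   widen by the total UMI length (see [preprocess_reads()]).
#' @return The input tibble with columns `trimmed` (NA when rejected) and
#'   `status` (`kept`, `low_quality`, `too_short`, `too_long`).
#' @export
trim_and_filter <- function(reads, adapter3, min_overlap = 5,
                            max_mismatch_rate = 0.15, q_min = 30,
                            len_min = 15, len_max = 40) {
  stopifnot(nzchar(adapter3), min_overlap >= 3,
            all(nchar(reads$sequence) == nchar(reads$quality)))
  ins_len <- locate_adapter(reads$sequence, adapter3, min_overlap,
                            max_mismatch_rate)
  ins_len[is.na(ins_len)] <- nchar(reads$sequence)[is.na(ins_len)]
  trimmed <- substr(reads$sequence, 1L, ins_len)
  status <- rep("kept", nrow(reads))
  status[phred_means(reads$quality) < q_min] <- "low_quality"
  status[status == "kept" & ins_len < len_min] <- "too_short"
  status[status == "kept" & ins_len > len_max] <- "too_long"
  reads$trimmed <- ifelse(status == "kept", trimmed, NA_character_)
  reads$status <- status
  reads
}

#' Extract UMIs from a trimmed sequence
#'
#' The 5' and 3' adapters carry degenerate bases; after trimming, the first
#' `umi5_len` and last `umi3_len` bases of the sequence are the molecular
#' identifier and the interior is the insert.
#'
#' @param trimmed character vector of trimmed sequences.
#' @param umi5_len,umi3_len UMI lengths (nt).
#' @return Tibble with columns `umi` (concatenated 5'+3' UMI) and `insert`.
#' @export
extract_umi <- function(trimmed, umi5_len, umi3_len) {
  if (any(nchar(trimmed) <= umi5_len + umi3_len)) {
    stop("sequence too short for UMI lengths", call. = FALSE)
  }
  n <- nchar(trimmed)
  tibble::tibble(
    umi = paste0(substr(trimmed, 1L, umi5_len),
                 substr(trimmed, n - umi3_len + 1L, n)),
    insert = substr(trimmed, umi5_len + 1L, n - umi3_len))
}

#' Deduplicate by UMI and collapse identical inserts
#'
#' A molecule is a distinct (insert, UMI) pair; identical insert sequences
#' are then collapsed for counting, so `unique_count` is the number of
#' distinct molecules observed for a sequence and `raw_count` the number of
#' reads (including PCR duplicates).
#'
#' @param molecules tibble with `insert` and `umi` columns.
#' @return Tibble (`sequence`, `unique_count`, `raw_count`) sorted by
#'   `unique_count` descending, ties broken by sequence lexicographically.
#' @export
dedup_and_collapse <- function(molecules) {
  if (nrow(molecules) == 0) {
    return(tibble::tibble(sequence = character(0), unique_count = integer(0),
                          raw_count = integer(0)))
  }
  molecules |>
    dplyr::summarise(unique_count = dplyr::n_distinct(.data$umi),
                     raw_count = dplyr::n(),
                     .by = "insert") |>
    dplyr::rename(sequence = "insert") |>
    dplyr::arrange(dplyr::desc(.data$unique_count), .data$sequence)
}

#' Preprocess a raw read set to collapsed unique reads
#'
#' Runs the full read-level pipeline: 3'-adapter trimming, mean-quality
#' filtering, UMI extraction, the insert length gate, and UMI deduplication
#' with sequence collapsing. The trimming stage length gate is widened by
#' the UMI lengths; the configured `len_min`/`len_max` gate is applied to
#' the UMI-free insert.
#'
#' @inheritParams trim_and_filter
#' @param umi5_len,umi3_len UMI lengths (nt).
#' @return A list with `collapsed` (see [dedup_and_collapse()]), `rejects`
#'   (tibble status/n summary over all reads) and `n_accepted`.
#' @export
preprocess_reads <- function(reads, adapter3, umi5_len = 6, umi3_len = 6,
                             min_overlap = 5, max_mismatch_rate = 0.15,
                             q_min = 30, len_min = 15, len_max = 40) {
  umi_tot <- umi5_len + umi3_len
  tr <- trim_and_filter(reads, adapter3, min_overlap, max_mismatch_rate,
                        q_min, len_min + umi_tot, len_max + umi_tot)
  kept <- tr[tr$status == "kept", , drop = FALSE]
  mol <- extract_umi(kept$trimmed, umi5_len, umi3_len)
  collapsed <- dedup_and_collapse(mol)
  rejects <- tr |>
    dplyr::count(.data$status, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(collapsed = collapsed, rejects = rejects, n_accepted = nrow(kept))
}
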