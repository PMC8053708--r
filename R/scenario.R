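SRNA_CLASSES <- c("miRNA", "rsRNA", "tsRNA", "pre_tsRNA", "piRNA", "snsRNA",
                  "snosRNA", "lncsRNA", "mt_tsRNA", "mRNA_sRNA", "other")

# fragment coordinates (1-based inclusive on the mature tRNA reference) for
# the five canonical tRNA-fragment types, given mature length L and the
# anticodon span
trna_fragment_coords <- function(type, L, ac_start, ac_end) {
  switch(type,
    tRF5 = c(1L, 20L),
    half5 = c(1L, ac_start + 1L),
    half3 = c(ac_end + 1L, L), # starts in the anticodon loop, <= 40 nt

    tRF3 = c(L - 17L, L),
    internal = c(20L, 50L),
    stop("unknown fragment type ", type))
}

draw_substring_species <- function(ref_tbl, n, len_min, len_max, prefix) {
  pick_ref <- sample(rep_len(seq_len(nrow(ref_tbl)), n))
  lens <- sample(len_min:len_max, n, replace = TRUE)
  reflen <- nchar(ref_tbl$sequence[pick_ref])
  lens <- pmin(lens, reflen)
  starts <- vapply(seq_len(n), function(i) {
    sample.int(reflen[i] - lens[i] + 1L, 1L)
  }, integer(1))
  tibble::tibble(
    species_id = sprintf("%s_%02d", prefix, seq_len(n)),
    sequence = substr(ref_tbl$sequence[pick_ref], starts,
                      starts + lens - 1L),
    parent_id = ref_tbl$ref_id[pick_ref],
    span_start = starts - 1L,
    span_end = starts - 1L + lens)
}

#' Build the default simulation scenario
#'
#' Generates a documented toy study: a random genome with cytosolic and
#' mitochondrial tRNA loci, per-class reference sets (miRNA, rRNA, mature and
#' precursor tRNA, piRNA clusters, snRNA, snoRNA, lncRNA, mRNA, other
#' ncRNA), and >= 8 species per small-RNA class (12 by default, 132 total)
#' with:
#' \itemize{
#'   \item every one of the 20 terminus states present in at least one
#'     species (class-typical states otherwise, e.g. m3G caps on snRNA
#'     fragments, 3'-cP and 3'-aminoacyl on tRNA halves);
#'   \item m1A, m3C and m1G sites at stoichiometries 0.25, 0.5 and 1.0
#'     (two species per kind x stoichiometry combination);
#'   \item abundance weights for `n_tissues` conditions drawn from a
#'     log-normal model, with one single-tissue species per class so that
#'     tissue-specificity identities can be checked.
#' }
#' Deterministic for a given seed.
#'
#' @param seed integer seed for scenario construction.
#' @param n_tissues number of tissues/conditions (>= 2).
#' @param species_per_class species generated for each of the 11 classes.
#' @return A list of class `cpa_scenario`: tibbles `species`, `methyl_sites`,
#'   `abundance`, `references`, plus `genome` (named character) and
#'   `trna_loci`.
#' @export
default_scenario <- function(seed = 1, n_tissues = 5, species_per_class = 12) {
  stopifnot(n_tissues >= 2, species_per_class >= 8)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  ## ---- references -------------------------------------------------------
  n_trna <- 12L
  raw_trna <- tibble::tibble(
    ref_id = sprintf("tRNA-%02d", seq_len(n_trna)),
    sequence = random_dna(n_trna, 72L),
    anticodon_start = 34L, anticodon_end = 36L,
    is_histidine = seq_len(n_trna) %in% c(5L, 11L),
    isodecoder = sprintf("iso-%s-%d",
                         rep(c("Ala", "Gly", "Glu", "His"),
                             length.out = n_trna),
                         seq_len(n_trna)))
  mature_trna <- build_mature_trna_refs(raw_trna)

  # genome: tRNA genes embedded in random intergenic spacers
  spacers <- random_dna(n_trna + 1L, 150L)
  pieces <- character(2L * n_trna + 1L)
  pieces[seq(1L, by = 2L, length.out = n_trna + 1L)] <- spacers
  pieces[seq(2L, by = 2L, length.out = n_trna)] <- raw_trna$sequence
  chr1 <- paste0(pieces, collapse = "")
  starts <- 150L * seq_len(n_trna) + 72L * (seq_len(n_trna) - 1L) + 1L
  trna_loci <- tibble::tibble(ref_id = raw_trna$ref_id, contig = "chr1",
                              start = starts, end = starts + 71L)

  n_mt <- 4L
  raw_mt <- tibble::tibble(
    ref_id = sprintf("mt-tRNA-%02d", seq_len(n_mt)),
    sequence = random_dna(n_mt, 68L),
    anticodon_start = 33L, anticodon_end = 35L,
    is_histidine = FALSE,
    isodecoder = sprintf("mt-iso-%d", seq_len(n_mt)))
  mt_spacers <- random_dna(n_mt + 1L, 120L)
  mt_pieces <- character(2L * n_mt + 1L)
  mt_pieces[seq(1L, by = 2L, length.out = n_mt + 1L)] <- mt_spacers
  mt_pieces[seq(2L, by = 2L, length.out = n_mt)] <- raw_mt$sequence
  chrM <- paste0(mt_pieces, collapse = "")
  genome <- c(chr1 = chr1, chrM = chrM)

  mature_mt <- build_mature_trna_refs(raw_mt, class = "mito_tRNA")
  pre_trna <- build_precursor_refs(genome, trna_loci)

  simple_refs <- function(class, n, len, prefix) {
    tibble::tibble(ref_id = sprintf("%s-%02d", prefix, seq_len(n)),
                   class = class, sequence = random_dna(n, len))
  }
  mirna_refs <- simple_refs("miRNA", species_per_class, 22L, "mir")
  rrna_refs <- tibble::tibble(
    ref_id = c("rRNA-5S", "rRNA-18S", "rRNA-28S"), class = "rRNA",
    sequence = c(random_dna(1, 120L), random_dna(1, 350L),
                 random_dna(1, 450L)))
  pirna_refs <- simple_refs("piRNA_cluster", 2L, 600L, "piC")
  snrna_refs <- simple_refs("snRNA", 3L, 160L, "snRNA")
  snorna_refs <- simple_refs("snoRNA", 3L, 130L, "snoRNA")
  lncrna_refs <- simple_refs("lncRNA", 3L, 400L, "lnc")
  mrna_refs <- simple_refs("mRNA", 3L, 400L, "mRNA")
  other_refs <- simple_refs("other_ncRNA", 3L, 250L, "ncRNA")
  genome_refs <- tibble::tibble(ref_id = names(genome), class = "genome",
                                sequence = unname(genome))

  references <- as_reference_tbl(
    mirna_refs, rrna_refs, mature_trna, pre_trna, pirna_refs, mature_mt,
    lncrna_refs, snrna_refs, snorna_refs, mrna_refs, other_refs, genome_refs)

  ## ---- species ----------------------------------------------------------
  k <- species_per_class
  mirna_sp <- tibble::tibble(
    species_id = sprintf("sp_miRNA_%02d", seq_len(k)),
    sequence = mirna_refs$sequence,
    parent_id = mirna_refs$ref_id,
    span_start = 0L, span_end = 22L)

  frag_species <- function(mature, n, prefix, parent_prefix_n) {
    types <- rep_len(c("tRF5", "half5", "half3", "tRF3", "internal"), n)
    ridx <- rep_len(seq_len(nrow(mature)), n)
    coords <- purrr::map2(types, ridx, function(ty, ri) {
      trna_fragment_coords(ty, nchar(mature$sequence[ri]),
                           mature$anticodon_start[ri],
                           mature$anticodon_end[ri])
    })
    tibble::tibble(
      species_id = sprintf("sp_%s_%02d", prefix, seq_len(n)),
      sequence = substr(mature$sequence[ridx],
                        purrr::map_int(coords, 1),
                        purrr::map_int(coords, 2)),
      parent_id = mature$ref_id[ridx],
      span_start = purrr::map_int(coords, 1) - 1L,
      span_end = purrr::map_int(coords, 2))
  }
  tsrna_sp <- frag_species(mature_trna, k, "tsRNA")
  mt_sp <- frag_species(mature_mt, k, "mt_tsRNA")

  # precursor fragments: 5' leaders and 3' trailers crossing the flanks
  pre_idx <- rep_len(seq_len(nrow(pre_trna)), k)
  pre_kind <- rep_len(c("leader5", "trailer3"), k)
  pre_coords <- purrr::map2(pre_kind, pre_idx, function(kd, ri) {
    ms <- pre_trna$mature_start[ri]
    me <- pre_trna$mature_end[ri]
    if (kd == "leader5") c(ms - 26L, ms + 9L) else c(me - 9L, me + 23L)
  })
  pre_sp <- tibble::tibble(
    species_id = sprintf("sp_pre_tsRNA_%02d", seq_len(k)),
    sequence = substr(pre_trna$sequence[pre_idx],
                      purrr::map_int(pre_coords, 1),
                      purrr::map_int(pre_coords, 2)),
    parent_id = pre_trna$ref_id[pre_idx],
    span_start = purrr::map_int(pre_coords, 1) - 1L,
    span_end = purrr::map_int(pre_coords, 2))

  rsrna_sp <- draw_substring_species(rrna_refs, k, 18L, 40L, "sp_rsRNA")
  pirna_sp <- draw_substring_species(pirna_refs, k, 26L, 31L, "sp_piRNA")
  snsrna_sp <- draw_substring_species(snrna_refs, k, 16L, 40L, "sp_snsRNA")
  snosrna_sp <- draw_substring_species(snorna_refs, k, 16L, 40L, "sp_snosRNA")
  lncsrna_sp <- draw_substring_species(lncrna_refs, k, 16L, 40L, "sp_lncsRNA")
  mrna_sp <- draw_substring_species(mrna_refs, k, 16L, 40L, "sp_mRNA_sRNA")
  other_sp <- draw_substring_species(other_refs, k, 16L, 40L, "sp_other")

  class_tbls <- list(miRNA = mirna_sp, rsRNA = rsrna_sp, tsRNA = tsrna_sp,
                     pre_tsRNA = pre_sp, piRNA = pirna_sp,
                     snsRNA = snsrna_sp, snosRNA = snosrna_sp,
                     lncsRNA = lncsrna_sp, mt_tsRNA = mt_sp,
                     mRNA_sRNA = mrna_sp, other = other_sp)
  species <- dplyr::bind_rows(class_tbls, .id = "parent_class")
  species <- species[, c("species_id", "sequence", "parent_class",
                         "parent_id", "span_start", "span_end")]
  if (anyDuplicated(species$sequence)) {
    stop("species sequence collision in scenario; change the seed")
  }

  ## ---- terminus states --------------------------------------------------
  # class-typical terminus states; tRNA-, rRNA- and snoRNA-derived classes
  # keep a large (P, OH) share because methylated species are placed there
  class_states <- list(
    miRNA = list(c("P", "OH")),
    rsRNA = list(c("P", "OH"), c("P", "OH"), c("OH", "P"), c("P", "cP")),
    tsRNA = list(c("P", "OH"), c("P", "OH"), c("OH", "P"), c("P", "cP"),
                 c("P", "aa"), c("P", "OH")),
    pre_tsRNA = list(c("ppp", "OH"), c("P", "OH"), c("OH", "OH")),
    piRNA = list(c("P", "OH")),
    snsRNA = list(c("cap_m3G", "OH"), c("cap_m7G", "OH"), c("P", "OH")),
    snosRNA = list(c("cap_m3G", "OH"), c("P", "OH"), c("P", "OH"),
                   c("OH", "OH")),
    lncsRNA = list(c("cap_m7G", "OH"), c("ppp", "OH"), c("P", "P")),
    mt_tsRNA = list(c("P", "OH"), c("P", "OH"), c("OH", "cP"), c("P", "cP")),
    mRNA_sRNA = list(c("cap_m7G", "OH"), c("P", "OH"), c("ppp", "P")),
    other = list(c("P", "OH"), c("OH", "OH")))
  st <- purrr::map(species$parent_class, function(cl) NULL)
  for (cl in names(class_tbls)) {
    rows <- which(species$parent_class == cl)
    st[rows] <- rep_len(class_states[[cl]], length(rows))
  }
  species$five_prime <- purrr::map_chr(st, 1)
  species$three_prime <- purrr::map_chr(st, 2)

  ## ---- methyl sites -----------------------------------------------------
  combos <- tidyr::expand_grid(kind = names(METHYL_KINDS),
                               stoichiometry = c(0.25, 0.5, 1.0))
  combos <- dplyr::bind_rows(combos, combos) # two species per combo
  cand <- which(species$parent_class %in%
                  c("tsRNA", "mt_tsRNA", "rsRNA", "snosRNA") &
                species$five_prime == "P" & species$three_prime == "OH")
  methyl <- list()
  used <- integer(0)
  # a methylation mark belongs to a parent position: only positions no
  # sibling species overlaps are usable, otherwise molecules of the
  # unmethylated sibling would dilute the site's mismatch signal
  free_positions <- function(s) {
    sib <- which(species$parent_id == species$parent_id[s])
    sib <- setdiff(sib, s)
    p_all <- (species$span_start[s] + 1L):species$span_end[s]
    covered <- rep(FALSE, length(p_all))
    for (o in sib) {
      covered <- covered |
        (p_all > species$span_start[o] & p_all <= species$span_end[o])
    }
    p_all[!covered] - species$span_start[s] # 1-based within the species
  }
  for (i in seq_len(nrow(combos))) {
    base <- METHYL_KINDS[[combos$kind[i]]]
    found <- FALSE
    for (s in setdiff(cand, used)) {
      seq_s <- species$sequence[s]
      pos <- which(strsplit(seq_s, "")[[1]] == base)
      pos <- pos[pos >= 4 & pos <= nchar(seq_s) - 3]
      pos <- intersect(pos, free_positions(s))
      if (length(pos)) {
        methyl[[length(methyl) + 1L]] <- tibble::tibble(
          species_id = species$species_id[s],
          offset = pos[ceiling(length(pos) / 2)] - 1L,
          kind = combos$kind[i],
          stoichiometry = combos$stoichiometry[i])
        used <- c(used, s)
        found <- TRUE
        break
      }
    }
    if (!found) stop("could not place methyl site for ", combos$kind[i])
  }
  methyl_sites <- dplyr::bind_rows(methyl)

  ## ---- ensure all 20 terminus states appear -----------------------------
  pair_key <- paste(species$five_prime, species$three_prime)
  all_pairs <- all_terminus_states()
  missing <- which(!paste(all_pairs$five_prime, all_pairs$three_prime)
                   %in% pair_key)
  if (length(missing)) {
    takeover <- setdiff(
      which(species$five_prime == "P" & species$three_prime == "OH" &
              !species$species_id %in% methyl_sites$species_id &
              !species$parent_class %in% c("miRNA", "piRNA")),
      integer(0))
    stopifnot(length(takeover) >= length(missing))
    # spread the overwrites across classes for realism
    takeover <- takeover[order(seq_along(takeover) %% 7)]
    for (j in seq_along(missing)) {
      species$five_prime[takeover[j]] <- all_pairs$five_prime[missing[j]]
      species$three_prime[takeover[j]] <- all_pairs$three_prime[missing[j]]
    }
  }

  ## ---- abundance --------------------------------------------------------
  tissues <- sprintf("tissue_%d", seq_len(n_tissues))
  base_w <- stats::rlnorm(nrow(species), meanlog = log(100), sdlog = 0.6)
  ab <- tidyr::expand_grid(species_id = species$species_id,
                           condition = tissues)
  ab$weight <- rep(base_w, each = n_tissues) *
    stats::rlnorm(nrow(ab), meanlog = 0, sdlog = 0.4)
  # one single-tissue species per class (never a methylated one)
  single <- species |>
    dplyr::filter(!.data$species_id %in% methyl_sites$species_id) |>
    dplyr::group_by(.data$parent_class) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::pull("species_id")
  home <- tissues[1L + (seq_along(single) %% n_tissues)]
  for (j in seq_along(single)) {
    off <- ab$species_id == single[j] & ab$condition != home[j]
    ab$weight[off] <- 0
  }

  structure(list(species = species, methyl_sites = methyl_sites,
                 abundance = ab, references = references,
                 genome = genome, trna_loci = trna_loci,
                 tissues = tissues, seed = as.integer(seed)),
            class = "cpa_scenario")
}

#' @export
print.cpa_scenario <- function(x, ...) {
  cat("<scenario> seed", x$seed, "|", nrow(x$species), "species in",
      length(unique(x$species$parent_class)), "classes |",
      nrow(x$methyl_sites), "methyl sites |",
      length(x$tissues), "tissues\n")
  invisible(x)
}

#' Write a scenario's references and tables to disk
#'
#' Emits the reference FASTA, the reference metadata TSV (ref_id, class,
#' anticodon_start, anticodon_end, is_histidine, isodecoder, mature_start,
#' mature_end), and the species / methylation / abundance ground-truth TSVs.
#'
#' @param scenario a [default_scenario()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- scenario$references
  seqs <- Biostrings::DNAStringSet(refs$sequence)
  names(seqs) <- refs$ref_id
  Biostrings::writeXStringSet(seqs, file.path(dir, "references.fasta"))
  readr::write_tsv(refs[, setdiff(names(refs), "sequence")],
                   file.path(dir, "references.tsv"))
  readr::write_tsv(scenario$species, file.path(dir, "species.tsv"))
  readr::write_tsv(scenario$methyl_sites, file.path(dir, "methyl_sites.tsv"))
  readr::write_tsv(scenario$abundance, file.path(dir, "abundance.tsv"))
  invisible(dir)
}
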