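DNA_BASES <- c("A", "C", "G", "T")

# Vectorized random DNA strings of a common length.
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  if (len == 0) return(rep("", n))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Substitute the base at `pos` of each string with a uniformly chosen
# different base. Vectorized over molecules; loops only over affected rows.
substitute_base <- function(seqs, pos) {
  for (i in seq_along(seqs)) {
    old <- substr(seqs[i], pos[i], pos[i])
    new <- sample(setdiff(DNA_BASES, old), 1)
    substr(seqs[i], pos[i], pos[i]) <- new
  }
  seqs
}

# Apply per-base sequencing errors at `rate` to a character vector.
apply_sequencing_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    for (p in sample.int(lens[i], n_err[i])) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1)
    }
  }
  seqs
}

#' Reverse transcribe molecules through residual methylated sites
#'
#' Models TGIRT behaviour at residual m1A/m3C/m1G sites: at each such site,
#' independently, the polymerase aborts with probability `stop_rate`
#' (the truncated cDNA lacks the 5'-adapter complement and cannot amplify, so
#' the molecule is dropped); otherwise it misincorporates with probability
#' `misinc_rate`, replacing the templated base by a uniformly chosen
#' different base. Per-base sequencing error is applied afterwards at
#' `seq_error_rate`.
#'
#' @param molecules tibble with a `sequence` column, one row per molecule;
#'   other columns are carried through.
#' @param sites tibble of residual methylated sites with columns `molecule`
#'   (row index into `molecules`) and `offset` (0-based position within the
#'   molecule sequence).
#' @param cfg a [sim_config()]; uses `stop_rate`, `misinc_rate`,
#'   `seq_error_rate`. Seed the RNG before calling.
#' @return `molecules` with dropped rows removed, a logical `misinc` column
#'   marking molecules that carry at least one misincorporation, and
#'   `sequence` rewritten as cDNA-equivalent read-out.
#' @export
reverse_transcribe <- function(molecules, sites, cfg) {
  stopifnot(inherits(cfg, "cpa_sim_config"), "sequence" %in% names(molecules))
  n <- nrow(molecules)
  misinc_flag <- rep(FALSE, n)
  dropped <- rep(FALSE, n)
  if (!is.null(sites) && nrow(sites) > 0) {
    stopifnot(all(sites$offset >= 0),
              all(sites$offset < nchar(molecules$sequence[sites$molecule])))
    stop_here <- stats::runif(nrow(sites)) < cfg$stop_rate
    mis_here <- !stop_here & stats::runif(nrow(sites)) < cfg$misinc_rate
    dropped[unique(sites$molecule[stop_here])] <- TRUE
    mis <- sites[mis_here & !dropped[sites$molecule], , drop = FALSE]
    if (nrow(mis) > 0) {
      molecules$sequence[mis$molecule] <-
        substitute_base(molecules$sequence[mis$molecule], mis$offset + 1L)
      misinc_flag[mis$molecule] <- TRUE
    }
  }
  molecules$misinc <- misinc_flag
  out <- molecules[!dropped, , drop = FALSE]
  out$sequence <- apply_sequencing_errors(out$sequence, cfg$seq_error_rate)
  out
}

# Draw per-molecule methylation status from per-site stoichiometry, one row
# per methylated molecule-site: columns molecule, offset.
draw_methylation <- function(mol_species, methyl_sites) {
  if (is.null(methyl_sites) || nrow(methyl_sites) == 0) {
    return(tibble::tibble(molecule = integer(0), offset = integer(0)))
  }
  hits <- dplyr::inner_join(
    tibble::tibble(molecule = seq_along(mol_species),
                   species_id = mol_species),
    methyl_sites[, c("species_id", "offset", "stoichiometry")],
    by = "species_id", relationship = "many-to-many")
  keep <- stats::runif(nrow(hits)) < hits$stoichiometry
  hits[keep, c("molecule", "offset")]
}

#' Simulate one sequencing library under a treatment plan
#'
#' Composes the generative model end to end: molecules are drawn from the
#' species table proportionally to their abundance in `condition`; enzyme
#' treatments convert termini and (with AlkB) erase methyl marks; molecules
#' that fail [is_ligatable()] are discarded without redrawing, so library
#' depth reflects ligatability; survivors receive 5'/3' UMIs and adapters,
#' pass [reverse_transcribe()], are PCR-duplicated (geometric copy count with
#' mean `pcr_dup_mean`) and emitted as FASTQ-style records with constant
#' base quality (a configurable fraction gets uniformly low quality instead).
#'
#' @param scenario a scenario as produced by [default_scenario()]: a list
#'   with `species`, `methyl_sites` and `abundance` tibbles.
#' @param condition condition/tissue label selecting the abundance column.
#' @param plan a [treatment_plan()].
#' @param cfg a [sim_config()]. The library RNG seed is derived
#'   deterministically from `cfg$seed`, the plan label and the condition.
#' @return A list with `reads` (tibble: id, sequence, quality), `truth`
#'   (per-species tibble: species_id, treated five/three state, n_molecules
#'   drawn, n_ligated, n_sequenced post-RT, n_reads emitted incl. PCR
#'   copies) and `n_molecules_sequenced` (the pre-PCR molecule count that
#'   UMI deduplication should recover).
#' @export
simulate_library <- function(scenario, condition, plan, cfg) {
  stopifnot(inherits(cfg, "cpa_sim_config"), inherits(plan, "cpa_plan"))
  species <- scenario$species
  if (is.null(species) || nrow(species) == 0) stop("empty species list")
  if (cfg$n_reads <= 0) stop("n_reads must be positive")
  ab <- scenario$abundance
  ab <- ab[ab$condition == condition, ]
  if (nrow(ab) == 0 || sum(ab$weight) <= 0) {
    stop("no species with positive abundance in condition ", condition)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_subseed(cfg$seed, plan$label, condition))

  # molecule draws proportional to abundance
  w <- ab$weight[match(species$species_id, ab$species_id)]
  w[is.na(w)] <- 0
  idx <- sample.int(nrow(species), cfg$n_reads, replace = TRUE, prob = w)
  mol <- tibble::tibble(
    species_id = species$species_id[idx],
    sequence = species$sequence[idx],
    five_prime = species$five_prime[idx],
    three_prime = species$three_prime[idx])
  n_drawn <- table(factor(mol$species_id, levels = species$species_id))

  # enzymatic conversions, then per-molecule methylation and demethylation
  mol <- apply_treatments(mol, plan, cfg$enzyme_efficiencies)
  msites <- draw_methylation(mol$species_id, scenario$methyl_sites)
  if (isTRUE(plan$alkb) && nrow(msites) > 0) {
    msites <- msites[stats::runif(nrow(msites)) >= cfg$alkb_efficiency, ,
                     drop = FALSE]
  }

  lig <- is_ligatable(mol)
  keep <- which(lig)
  mol_l <- mol[keep, , drop = FALSE]
  n_ligated <- table(factor(mol_l$species_id, levels = species$species_id))
  msites <- msites[msites$molecule %in% keep, , drop = FALSE]
  msites$molecule <- match(msites$molecule, keep)

  mol_l$.res_sites <- tabulate2(msites$molecule, nrow(mol_l))
  seq_out <- reverse_transcribe(mol_l, msites, cfg)
  n_seq <- table(factor(seq_out$species_id, levels = species$species_id))
  n_mol_sequenced <- nrow(seq_out)

  # UMIs, adapters, PCR duplication, read emission
  umi5 <- random_dna(nrow(seq_out), cfg$umi5_len)
  umi3 <- random_dna(nrow(seq_out), cfg$umi3_len)
  copies <- if (cfg$pcr_dup_mean <= 1) rep(1L, nrow(seq_out)) else
    1L + stats::rgeom(nrow(seq_out), prob = 1 / cfg$pcr_dup_mean)
  construct <- paste0(umi5, seq_out$sequence, umi3, cfg$adapter3)
  rep_idx <- rep.int(seq_len(nrow(seq_out)), copies)
  reads <- construct[rep_idx]
  # pad short constructs (sequencer reads past the adapter) and clip long ones
  pad <- cfg$read_length - nchar(reads)
  need <- pad > 0
  if (any(need)) {
    reads[need] <- paste0(reads[need],
                          strrep("A", pad[need]))
  }
  reads <- substr(reads, 1L, cfg$read_length)
  reads <- apply_sequencing_errors(reads, cfg$seq_error_rate)

  qual_hi <- strrep(intToUtf8(33L + cfg$q_high), cfg$read_length)
  qual_lo <- strrep(intToUtf8(33L + cfg$q_low), cfg$read_length)
  low <- stats::runif(length(reads)) < cfg$low_quality_fraction
  n_emitted <- table(factor(rep(seq_out$species_id, copies),
                            levels = species$species_id))

  # species-level treated termini (deterministic limit of the plan)
  treated <- apply_treatments(species[, c("five_prime", "three_prime")],
                              plan, c(deacylate = 1, cap_clip = 1, pnk = 1))
  truth <- tibble::tibble(
    species_id = species$species_id,
    five_prime = treated$five_prime,
    three_prime = treated$three_prime,
    n_molecules = as.integer(n_drawn),
    n_ligated = as.integer(n_ligated),
    n_sequenced = as.integer(n_seq),
    n_reads = as.integer(n_emitted))

  list(
    reads = tibble::tibble(
      id = sprintf("%s_%s_read%07d", plan$label, condition,
                   seq_along(reads)),
      sequence = reads,
      quality = ifelse(low, qual_lo, qual_hi)),
    truth = truth,
    n_molecules_sequenced = n_mol_sequenced,
    plan = plan$label,
    condition = condition)
}

tabulate2 <- function(idx, n) {
  if (length(idx) == 0) return(integer(n))
  tabulate(idx, nbins = n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
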