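# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_scenario <- function() fixture("scenario", function() {
  default_scenario(seed = 1)
})

# A modest four-plan pipeline run shared by several test files.
small_run <- function() fixture("run", function() {
  run_pipeline(small_scenario(),
               run_config(seed = 11, sim = list(n_reads = 30000)))
})

# Brute-force Hamming-scan aligner: the independent oracle for align_read.
# Scans every offset of every reference, sense strand, and applies the same
# tie-break (fewest mismatches, then reference order, then leftmost start).
brute_force_align <- function(seq, references, max_mismatches = 1) {
  best <- NULL
  L <- nchar(seq)
  qraw <- charToRaw(seq)
  for (r in seq_len(nrow(references))) {
    refseq <- references$sequence[r]
    rlen <- nchar(refseq)
    if (rlen < L) next
    rraw <- charToRaw(refseq)
    for (s in seq_len(rlen - L + 1L)) {
      mm <- sum(rraw[s:(s + L - 1L)] != qraw)
      if (mm <= max_mismatches) {
        cand <- list(ref_idx = r, start = s - 1L, mismatches = mm)
        if (is.null(best) ||
            mm < best$mismatches ||
            (mm == best$mismatches && r < best$ref_idx) ||
            (mm == best$mismatches && r == best$ref_idx &&
               cand$start < best$start)) {
          best <- cand
        }
      }
    }
  }
  best
}

# Random mutation of one position of a string (guaranteed to change it).
mutate_one <- function(seq, pos = NULL) {
  if (is.null(pos)) pos <- sample.int(nchar(seq), 1)
  old <- substr(seq, pos, pos)
  substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  seq
}

# Truth helpers for the default scenario: species ids present in a
# condition, split by the chemistry the treatments reveal.
truth_sets <- function(scenario, condition = "tissue_1") {
  ab <- scenario$abundance
  present <- ab$species_id[ab$condition == condition & ab$weight > 0]
  sp <- scenario$species[scenario$species$species_id %in% present, ]
  meth <- scenario$methyl_sites
  list(
    species = sp,
    capped = sp$species_id[sp$five_prime %in% c("cap_m7G", "cap_m3G",
                                                "ppp")],
    pnk_dep = sp$species_id[sp$five_prime == "OH" |
                              sp$three_prime %in% c("P", "cP")],
    methylated_hi = intersect(
      meth$species_id[meth$stoichiometry == 1], sp$species_id),
    clean = sp$species_id[sp$five_prime == "P" & sp$three_prime == "OH" &
                            !sp$species_id %in% meth$species_id])
}

species_sequences <- function(scenario, ids) {
  scenario$species$sequence[match(ids, scenario$species$species_id)]
}
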