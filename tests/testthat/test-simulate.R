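test_that("reverse transcription is the identity without sites or errors", {
  cfg <- sim_config(seed = 1, seq_error_rate = 0)
  mol <- tibble::tibble(sequence = c("ACGTACGTACGTACGT", "GGGTTTAAACCC"))
  out <- reverse_transcribe(mol, NULL, cfg)
  expect_equal(out$sequence, mol$sequence)
  expect_false(any(out$misinc))
})

test_that("a certain misincorporation substitutes exactly the site base", {
  cfg <- sim_config(seed = 1, seq_error_rate = 0, misinc_rate = 1,
                    stop_rate = 0)
  mol <- tibble::tibble(sequence = "ACGTACGTACGTACGT")
  sites <- tibble::tibble(molecule = 1L, offset = 4L)
  withr::with_seed(7, out <- reverse_transcribe(mol, sites, cfg))
  expect_equal(nrow(out), 1L)
  expect_true(out$misinc)
  diff <- which(strsplit(out$sequence, "")[[1]] !=
                  strsplit(mol$sequence, "")[[1]])
  expect_equal(diff, 5L) # 0-based offset 4
})

test_that("a certain stop drops the molecule", {
  cfg <- sim_config(seed = 1, seq_error_rate = 0, stop_rate = 1)
  mol <- tibble::tibble(sequence = c("ACGTACGTACGTACGT", "TTTTGGGGCCCCAAAA"))
  sites <- tibble::tibble(molecule = 1L, offset = 2L)
  withr::with_seed(7, out <- reverse_transcribe(mol, sites, cfg))
  expect_equal(out$sequence, "TTTTGGGGCCCCAAAA")
})

test_that("a clean ligatable species yields perfect-copy reads", {
  sc <- list(
    species = tibble::tibble(
      species_id = "s1", sequence = strrep("ACGT", 6),
      parent_class = "other", parent_id = "r1",
      span_start = 0L, span_end = 24L,
      five_prime = "P", three_prime = "OH"),
    methyl_sites = NULL,
    abundance = tibble::tibble(species_id = "s1", condition = "c1",
                               weight = 1))
  cfg <- sim_config(seed = 9, n_reads = 100, seq_error_rate = 0,
                    pcr_dup_mean = 1, low_quality_fraction = 0)
  lib <- simulate_library(sc, "c1", plan_from_label("untreated"), cfg)
  expect_equal(nrow(lib$reads), 100L)
  inserts <- substr(lib$reads$sequence, cfg$umi5_len + 1L,
                    cfg$umi5_len + 24L)
  expect_true(all(inserts == strrep("ACGT", 6)))
  expect_equal(lib$truth$n_reads, 100L)
})

test_that("a capped species vanishes without Cap-Clip", {
  sc <- list(
    species = tibble::tibble(
      species_id = "s1", sequence = strrep("ACGT", 6),
      parent_class = "other", parent_id = "r1",
      span_start = 0L, span_end = 24L,
      five_prime = "cap_m7G", three_prime = "OH"),
    methyl_sites = NULL,
    abundance = tibble::tibble(species_id = "s1", condition = "c1",
                               weight = 1))
  cfg <- sim_config(seed = 9, n_reads = 50)
  lib <- simulate_library(sc, "c1", plan_from_label("PA"), cfg)
  expect_equal(nrow(lib$reads), 0L)
  lib2 <- simulate_library(sc, "c1", plan_from_label("CPA"), cfg)
  expect_gt(nrow(lib2$reads), 0L)
})

test_that("library simulation is byte-identical on rerun with one seed", {
  sc <- small_scenario()
  cfg <- sim_config(seed = 123, n_reads = 2000)
  for (label in c("CPA", "CA")) {
    a <- simulate_library(sc, "tissue_1", plan_from_label(label), cfg)
    b <- simulate_library(sc, "tissue_1", plan_from_label(label), cfg)
    expect_identical(a$reads, b$reads)
    expect_identical(a$truth, b$truth)
  }
  # different plans draw from different sub-seeded streams
  a <- simulate_library(sc, "tissue_1", plan_from_label("CPA"), cfg)
  b <- simulate_library(sc, "tissue_1", plan_from_label("CA"), cfg)
  expect_false(identical(a$reads$sequence[1], b$reads$sequence[1]))
})

test_that("the default scenario covers classes, states and stoichiometries", {
  sc <- small_scenario()
  counts <- table(sc$species$parent_class)
  expect_true(all(counts >= 8))
  expect_setequal(names(counts),
                  c("miRNA", "rsRNA", "tsRNA", "pre_tsRNA", "piRNA",
                    "snsRNA", "snosRNA", "lncsRNA", "mt_tsRNA",
                    "mRNA_sRNA", "other"))
  pairs <- unique(paste(sc$species$five_prime, sc$species$three_prime))
  expect_equal(length(pairs), 20L)
  ms <- sc$methyl_sites
  expect_setequal(unique(ms$kind), c("m1A", "m3C", "m1G"))
  expect_setequal(unique(ms$stoichiometry), c(0.25, 0.5, 1.0))
  # each kind x stoichiometry combination is simulated
  expect_equal(nrow(unique(ms[, c("kind", "stoichiometry")])), 9L)
  # methylated base matches the kind
  base_at <- substr(sc$species$sequence[match(ms$species_id,
                                              sc$species$species_id)],
                    ms$offset + 1L, ms$offset + 1L)
  expect_equal(base_at, unname(METHYL_KINDS[ms$kind]))
  # single-tissue species exist for TSI identities
  ab <- sc$abundance
  n_tissues_expr <- tapply(ab$weight > 0, ab$species_id, sum)
  expect_gt(sum(n_tissues_expr == 1), 0)
})

test_that("the default scenario is deterministic in its seed", {
  a <- default_scenario(seed = 4)
  b <- default_scenario(seed = 4)
  expect_identical(a$species, b$species)
  expect_identical(a$references, b$references)
  expect_identical(a$abundance, b$abundance)
})

test_that("species sequences equal their parent subsequence", {
  sc <- small_scenario()
  refs <- sc$references
  sp <- sc$species
  parent_seq <- refs$sequence[match(sp$parent_id, refs$ref_id)]
  expect_equal(substr(parent_seq, sp$span_start + 1L, sp$span_end),
               sp$sequence)
  expect_true(all(nchar(sp$sequence) >= 15 & nchar(sp$sequence) <= 45))
})

test_that("scenario files round-trip through disk", {
  dir <- withr::local_tempdir()
  sc <- small_scenario()
  write_scenario(sc, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "references.fasta"))
  expect_equal(length(fa), nrow(sc$references))
  expect_equal(unname(as.character(fa)), sc$references$sequence)
  meta <- readr::read_tsv(file.path(dir, "references.tsv"),
                          show_col_types = FALSE)
  expect_equal(meta$ref_id, sc$references$ref_id)
})

test_that("fastq round-trips through Biostrings", {
  path <- withr::local_tempfile(fileext = ".fastq")
  reads <- tibble::tibble(id = c("r1", "r2"),
                          sequence = c("ACGTACGTAAAA", "GGGGTTTTCCCC"),
                          quality = c(strrep("F", 12), strrep("5", 12)))
  write_fastq_tbl(reads, path)
  back <- read_fastq_tbl(path)
  expect_equal(back, reads)
})
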