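test_that("mature tRNA references gain CCA, and His tRNAs a 5' G", {
  raw <- tibble::tibble(
    ref_id = c("t1", "tHis"),
    sequence = c(strrep("A", 72), strrep("G", 72)),
    anticodon_start = c(34L, 33L), anticodon_end = c(36L, 35L),
    is_histidine = c(FALSE, TRUE),
    isodecoder = c("iso1", "isoH"))
  out <- build_mature_trna_refs(raw)
  expect_equal(nchar(out$sequence), c(75L, 76L))
  expect_true(all(endsWith(out$sequence, "CCA")))
  expect_true(startsWith(out$sequence[2], "G"))
  expect_equal(out$anticodon_start, c(34L, 34L)) # His span shifted +1
  expect_equal(out$anticodon_end, c(36L, 36L))
  # CCA is appended even if the raw gene already ends in CCA
  raw2 <- tibble::tibble(ref_id = "t2",
                         sequence = paste0(strrep("A", 69), "CCA"),
                         anticodon_start = 34L, anticodon_end = 36L,
                         is_histidine = FALSE)
  expect_true(endsWith(build_mature_trna_refs(raw2)$sequence, "CCACCA"))
  expect_equal(nrow(build_mature_trna_refs(raw[0, ])), 0L)
})

test_that("precursor references span +/- 100 bp, clipped at contig edges", {
  genome <- c(chr = random_dna(1, 1500))
  loci <- tibble::tibble(ref_id = c("t1", "t2"), contig = "chr",
                         start = c(1001L, 30L), end = c(1072L, 101L))
  out <- build_precursor_refs(genome, loci)
  expect_equal(nchar(out$sequence), c(272L, 201L + 29L - 29L))
  expect_equal(nchar(out$sequence)[2], 29L + 72L + 100L) # clipped upstream
  expect_equal(out$mature_start, c(101L, 30L))
  expect_equal(out$sequence[1], unname(substr(genome, 901, 1172)))
  expect_error(
    build_precursor_refs(genome, tibble::tibble(ref_id = "x",
                                                contig = "chrX",
                                                start = 1L, end = 10L)),
    "missing contig")
})

test_that("align_read finds exact and one-mismatch placements", {
  withr::with_seed(21, {
    refs <- tibble::tibble(ref_id = c("r1", "r2"),
                           sequence = c(random_dna(1, 200),
                                        random_dna(1, 200)))
    read <- substr(refs$sequence[2], 50, 75)
    hit <- align_read(read, refs)
    expect_equal(hit$ref_id, "r2")
    expect_equal(hit$start, 49L)
    expect_equal(hit$mismatches, 0L)
    hit1 <- align_read(mutate_one(read, 10), refs)
    expect_equal(hit1$ref_id, "r2")
    expect_equal(hit1$start, 49L)
    expect_equal(hit1$mismatches, 1L)
    # two mismatches everywhere -> no hit
    none <- align_read(mutate_one(mutate_one(read, 3), 20), refs)
    expect_equal(nrow(none), 0L)
    # and never any hit at max_mismatches = 0 for the mutant
    expect_equal(nrow(align_read(mutate_one(read, 10), refs,
                                 max_mismatches = 0)), 0L)
  })
})

test_that("align_read agrees with the brute-force Hamming oracle", {
  withr::with_seed(99, {
    refs <- tibble::tibble(ref_id = sprintf("r%d", 1:6),
                           sequence = random_dna(6, 120))
    for (i in 1:300) {
      kind <- i %% 3
      if (kind == 0) {
        read <- random_dna(1, sample(15:30, 1)) # mostly unmappable
      } else {
        r <- sample(6, 1)
        len <- sample(15:30, 1)
        s <- sample(120 - len + 1, 1)
        read <- substr(refs$sequence[r], s, s + len - 1)
        if (kind == 2) read <- mutate_one(read)
      }
      got <- align_read(read, refs)
      want <- brute_force_align(read, refs)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L, label = paste("case", i))
      } else {
        expect_equal(got$ref_id, refs$ref_id[want$ref_idx],
                     label = paste("case", i))
        expect_equal(got$start, want$start, label = paste("case", i))
        expect_equal(got$mismatches, want$mismatches,
                     label = paste("case", i))
      }
    }
  })
})

test_that("cascade priority: shared sequences resolve by stage and gates", {
  shared22 <- random_dna(1, 22)
  shared30 <- paste0(shared22, random_dna(1, 8))
  trna_body <- paste0(random_dna(1, 20), shared30, random_dna(1, 22))
  refs <- as_reference_tbl(
    tibble::tibble(ref_id = "mir-1", class = "miRNA", sequence = shared22),
    tibble::tibble(ref_id = "tRNA-1", class = "cyto_tRNA",
                   sequence = trna_body, anticodon_start = 34L,
                   anticodon_end = 36L, is_histidine = FALSE),
    tibble::tibble(ref_id = "chr1", class = "genome",
                   sequence = paste0(random_dna(1, 100), trna_body,
                                     random_dna(1, 100))))
  db <- reference_db(refs)
  collapsed <- tibble::tibble(
    sequence = c(shared22, shared30, mutate_one(shared22, 11)),
    unique_count = c(5L, 4L, 3L), raw_count = c(5L, 4L, 3L))
  ann <- annotate_cascade(collapsed, db)
  got <- ann$hits[match(collapsed$sequence, ann$hits$sequence), ]
  # 22-nt read present in both miRNA and tRNA: miRNA stage wins
  expect_equal(got$class[1], "miRNA")
  # same sequence at 30 nt: outside the miRNA gate, lands on the tRNA
  expect_equal(got$class[2], "cyto_tRNA")
  # 1-mismatch miRNA look-alike: zero-mismatch miRNA stage refuses it;
  # it falls through to the first stage allowing a mismatch
  expect_equal(got$class[3], "cyto_tRNA")
  expect_equal(got$mismatches[3], 1L)
})

test_that("piRNA stage gates by length 24-32", {
  withr::with_seed(33, {
    pic <- random_dna(1, 300)
    refs <- as_reference_tbl(
      tibble::tibble(ref_id = "piC-1", class = "piRNA_cluster",
                     sequence = pic),
      tibble::tibble(ref_id = "chr1", class = "genome",
                     sequence = paste0(random_dna(1, 50), pic,
                                       random_dna(1, 50))))
    db <- reference_db(refs)
    collapsed <- tibble::tibble(
      sequence = c(substr(pic, 10, 37), substr(pic, 10, 31)), # 28 & 22 nt
      unique_count = c(2L, 2L), raw_count = c(2L, 2L))
    ann <- annotate_cascade(collapsed, db)
    got <- ann$hits[match(collapsed$sequence, ann$hits$sequence), ]
    expect_equal(got$class, c("piRNA_cluster", "genome"))
  })
})

test_that("annotation partitions the input reads", {
  run <- small_run()
  for (lib in run$libraries) {
    expect_equal(nrow(lib$hits) + nrow(lib$unannotated),
                 nrow(lib$collapsed))
    expect_equal(sort(c(lib$hits$sequence, lib$unannotated$sequence)),
                 sort(lib$collapsed$sequence))
  }
})

test_that("tsRNA typing follows the anticodon-loop boundary rules", {
  # 76-nt mature reference, anticodon 34-36 -> loop 32-38
  ref <- tibble::tibble(ref_id = "t1", class = "cyto_tRNA",
                        sequence = random_dna(1, 76),
                        anticodon_start = 34L, anticodon_end = 36L,
                        is_histidine = FALSE)
  mk_hit <- function(s1, e1) {
    tibble::tibble(sequence = substr(ref$sequence, s1, e1),
                   class = "cyto_tRNA", ref_id = "t1", start = s1 - 1L)
  }
  cases <- list(list(1, 34, "half5"), list(1, 20, "tRF5"),
                list(40, 76, "tRF3"), list(20, 50, "internal"),
                list(33, 76, "half3"))
  for (cs in cases) {
    expect_equal(classify_tsrna(mk_hit(cs[[1]], cs[[2]]), ref), cs[[3]],
                 label = sprintf("%d-%d", cs[[1]], cs[[2]]))
  }
  # precursor flanks type as leader/trailer
  pre <- tibble::tibble(ref_id = "p1", class = "pre_tRNA",
                        sequence = random_dna(1, 272),
                        mature_start = 101L, mature_end = 172L)
  hit <- tibble::tibble(sequence = substr(pre$sequence, 60, 90),
                        class = "pre_tRNA", ref_id = "p1", start = 59L)
  expect_equal(classify_tsrna(hit, pre), "leader5")
  tr <- tibble::tibble(sequence = substr(pre$sequence, 165, 200),
                       class = "pre_tRNA", ref_id = "p1", start = 164L)
  expect_equal(classify_tsrna(tr, pre), "trailer3")
  # anticodon span is required on tRNA classes
  bad <- ref
  bad$anticodon_start <- NA_integer_
  expect_error(classify_tsrna(mk_hit(1, 20), bad), "anticodon")
})

test_that("cascade annotates every zero-error read to its true class", {
  sc <- small_scenario()
  cfg <- sim_config(seed = 17, n_reads = 15000, seq_error_rate = 0,
                    misinc_rate = 0, stop_rate = 0,
                    low_quality_fraction = 0)
  lib <- simulate_library(sc, "tissue_1", plan_from_label("CPA"), cfg)
  pp <- preprocess_reads(lib$reads, cfg$adapter3)
  ann <- annotate_cascade(pp$collapsed, reference_db(sc$references))
  expect_equal(nrow(ann$unannotated), 0L)
  truth_class <- sc$species$parent_class[match(ann$hits$sequence,
                                               sc$species$sequence)]
  expect_false(anyNA(truth_class))
  expect_equal(ann$hits$srna_class, truth_class)
  expect_true(all(ann$hits$mismatches == 0L))
})
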