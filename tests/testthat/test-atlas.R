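test_that("TSI identities: single-tissue 1, uniform 0, worked row", {
  expect_equal(compute_tsi(c(80, 0, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(compute_tsi(rep(5, 9)), 0)
  expect_equal(compute_tsi(c(80, 10, 10, 0, 0, 0, 0, 0, 0)), 0.96875)
  expect_error(compute_tsi(rep(0, 5)), "all-zero")
  expect_error(compute_tsi(42))
})

test_that("TSI is scale invariant and within [0, 1]", {
  withr::with_seed(13, {
    for (i in 1:50) {
      x <- stats::rexp(sample(2:12, 1))
      t1 <- compute_tsi(x)
      expect_gte(t1, 0)
      expect_lte(t1, 1)
      expect_equal(compute_tsi(x * stats::runif(1, 0.01, 100)), t1)
    }
  })
})

test_that("TSI never decreases when mass moves into the max tissue", {
  withr::with_seed(14, {
    for (i in 1:25) {
      x <- stats::rexp(8)
      j <- which.max(x)
      k <- sample(setdiff(1:8, j), 1)
      y <- x
      shift <- y[k] * stats::runif(1)
      y[k] <- y[k] - shift
      y[j] <- y[j] + shift
      expect_gte(compute_tsi(y), compute_tsi(x) - 1e-12)
    }
  })
})

test_that("tissue_specificity summarizes a long table per sequence", {
  tbl <- tibble::tibble(
    sequence = rep(c("a", "b"), each = 3),
    srna_class = rep(c("miRNA", "tsRNA"), each = 3),
    library = rep(c("t1", "t2", "t3"), 2),
    rpm = c(90, 0, 0, 10, 10, 10))
  out <- tissue_specificity(tbl)
  expect_equal(out$tsi[out$sequence == "a"], 1)
  expect_equal(out$tsi[out$sequence == "b"], 0)
  expect_equal(out$max_tissue[out$sequence == "a"], "t1")
  expect_equal(out$max_value[out$sequence == "a"], 90)
  expect_equal(out$srna_class, c("miRNA", "tsRNA"))
})

test_that("enrichment applies class RPM floors and the TSI cut", {
  tsi_tbl <- tibble::tibble(
    sequence = c("s1", "s2", "s3", "s4", "s5"),
    srna_class = c("snosRNA", "snosRNA", "miRNA", "mt_tsRNA", "lncsRNA"),
    tsi = c(0.97, 0.99, 0.5, 0.96, 0.99),
    max_value = c(35, 25, 1000, 70, 60),
    max_tissue = "t1")
  out <- filter_and_enrich(tsi_tbl)
  # snosRNA floor 30: 35 passes, 25 does not
  expect_true("s1" %in% out$sequence)
  expect_false("s2" %in% out$sequence)
  # TSI 0.5 is never enriched regardless of expression
  expect_false("s3" %in% out$sequence)
  # mt_tsRNA floor is 70, exclusive
  expect_false("s4" %in% out$sequence)
  expect_true("s5" %in% out$sequence)
  expect_equal(out$rpm_floor, c(30, 50))
  # unknown classes fall back to the default floor of 20
  unk <- tibble::tibble(sequence = "u", srna_class = "piRNA", tsi = 0.99,
                        max_value = 21, max_tissue = "t1")
  expect_equal(nrow(filter_and_enrich(unk)), 1L)
})

test_that("single-tissue species reach TSI 1 in a multi-tissue run", {
  sc <- small_scenario()
  runs <- fixture("tissue_runs", function() {
    purrr::map(sc$tissues[1:3], function(ti) {
      run_pipeline(sc, run_config(seed = 23, plans = "CPA",
                                  condition = ti,
                                  sim = list(n_reads = 12000)))
    }) |> stats::setNames(sc$tissues[1:3])
  })
  expr <- dplyr::bind_rows(
    purrr::map(runs, function(r) {
      e <- r$expression
      e$library <- r$config$condition
      e
    }))
  tsi <- tissue_specificity(expr)
  ab <- sc$abundance[sc$abundance$weight > 0, ]
  n_expr <- tapply(ab$condition %in% sc$tissues[1:3], ab$species_id, sum)
  single_home <- names(n_expr)[n_expr == 1]
  single_seqs <- species_sequences(sc, single_home)
  got <- tsi$tsi[match(single_seqs, tsi$sequence)]
  got <- got[!is.na(got)] # species whose home tissue is outside the subset
  expect_gt(length(got), 0)
  expect_true(all(got >= 0.95))
})

test_that("per-class clustering matches hand Euclidean arithmetic", {
  tbl <- tibble::tibble(
    sequence = rep(c("a", "b"), each = 3),
    srna_class = "tsRNA",
    library = rep(c("t1", "t2", "t3"), 2),
    rpm = c(0, 0, 8, 8, 0, 0))
  cl <- cluster_by_class(tbl, min_rpm = 5)
  tree <- cl$trees$tsRNA$tree
  # distance between log2(x+1) rows (0,0,log2 9) and (log2 9,0,0)
  expect_equal(tree$height, sqrt(2 * log2(9)^2), tolerance = 1e-12)
  # identical rows merge at distance zero
  dup <- tibble::tibble(sequence = rep(c("a", "b"), each = 2),
                        srna_class = "x" , library = rep(c("t1", "t2"), 2),
                        rpm = c(30, 40, 30, 40))
  # class label outside the known set is fine for clustering input
  dup$srna_class <- "tsRNA"
  cl2 <- cluster_by_class(dup, min_rpm = 5)
  expect_equal(cl2$trees$tsRNA$tree$height, 0)
})

test_that("clustering is invariant to input row order", {
  withr::with_seed(15, {
    tbl <- tidyr::expand_grid(sequence = sprintf("s%02d", 1:12),
                              library = c("t1", "t2", "t3", "t4"))
    tbl$srna_class <- rep(c("tsRNA", "rsRNA"), each = 24)
    tbl$rpm <- stats::rlnorm(48, log(50), 1)
    cl1 <- cluster_by_class(tbl, min_rpm = 0)
    cl2 <- cluster_by_class(tbl[sample(nrow(tbl)), ], min_rpm = 0)
    for (cls in names(cl1$trees)) {
      expect_equal(cl1$trees[[cls]]$tree$merge, cl2$trees[[cls]]$tree$merge)
      expect_equal(cl1$trees[[cls]]$tree$height,
                   cl2$trees[[cls]]$tree$height)
    }
    # single-row classes yield a trivial tree
    lone <- cluster_by_class(tbl[tbl$sequence == "s01", ], min_rpm = 0)
    expect_null(lone$trees$tsRNA$tree)
    expect_equal(lone$trees$tsRNA$ids, "s01")
  })
})

test_that("prefilter keeps rows above 20 RPM in at least one tissue", {
  tbl <- tibble::tibble(sequence = c("lo", "lo", "hi", "hi"),
                        srna_class = "tsRNA",
                        library = rep(c("t1", "t2"), 2),
                        rpm = c(15, 19, 15, 21))
  cl <- cluster_by_class(tbl)
  expect_equal(cl$trees$tsRNA$ids, "hi")
})

test_that("differential species selection follows the t-test and FC gates", {
  a <- tibble::tibble(sequence = rep("s", 3), rep = 1:3,
                      rpm = c(100, 110, 90))
  b <- tibble::tibble(sequence = rep("s", 3), rep = 1:3,
                      rpm = c(10, 12, 8))
  out <- differential_species(a, b)
  expect_true(out$selected)
  expect_equal(out$direction, "A>B")
  expect_lt(out$p_value, 0.05)
  expect_gt(out$fold_change, 2)
  # identical groups are never selected
  same <- differential_species(a, a)
  expect_false(same$selected)
  # strong significance cannot rescue a sub-threshold fold change
  a2 <- b
  a2$rpm <- c(15.0, 15.1, 14.9)
  out2 <- differential_species(a2, b, fc_min = 2)
  expect_false(out2$selected)
  expect_error(differential_species(a[1, ], b), "2 replicates")
})

test_that("tidiers return tibbles with the advertised shapes", {
  a <- tibble::tibble(sequence = rep(c("s", "u"), each = 2), rep = c(1:2, 1:2),
                      rpm = c(100, 110, 5, 6))
  b <- tibble::tibble(sequence = rep(c("s", "u"), each = 2), rep = c(1:2, 1:2),
                      rpm = c(10, 12, 5, 6))
  d <- differential_species(a, b)
  expect_s3_class(tidy(d), "tbl_df")
  g <- glance(d)
  expect_equal(g$n_tested, 2L)
  expect_equal(g$n_selected + sum(!d$selected), 2L)
  tbl <- tidyr::expand_grid(sequence = sprintf("s%d", 1:6),
                            library = c("t1", "t2"))
  tbl$srna_class <- rep(c("tsRNA", "rsRNA"), each = 6)
  tbl$rpm <- rep(c(100, 30), 6)
  cl <- cluster_by_class(tbl, min_rpm = 0)
  td <- tidy(cl)
  expect_true(all(c("srna_class", "height", "node1") %in% names(td)))
  gl <- glance(cl)
  expect_equal(sum(gl$n_sequences), 6L)
})
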