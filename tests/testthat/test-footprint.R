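# correlation footprinting: filters, null matching, KS aggregation

test_that("filter grid boundary: count 5 in exactly 10 samples", {
  counts <- matrix(0, 2, 40, dimnames = list(NULL, sprintf("S%02d", 1:40)))
  counts[1, 1:10] <- 5     # locus passing (10,5) exactly
  counts[2, 1:25] <- 5     # locus passing (20,5)
  m <- make_lcm(counts)
  expect_equal(nrow(apply_filter(m, filter_spec(10, 5))$counts), 2L)
  expect_equal(nrow(apply_filter(m, filter_spec(20, 5))$counts), 1L)
  expect_equal(nrow(apply_filter(m, filter_spec(30, 5))$counts), 0L)
})

test_that("prepare_cohort removes shared loci and empty rows", {
  set.seed(71)
  c1 <- matrix(rpois(10 * 6, 5), 10, 6)
  c2 <- matrix(rpois(10 * 6, 5), 10, 6)
  m1 <- make_lcm(c1, "R1", offset = 0L)
  m2 <- make_lcm(c2, "R2", offset = 5000L)
  # plant one shared locus: same coordinates in both sets
  shared <- GRanges("chrT", IRanges::IRanges(20000L, 20020L), strand = "+")
  m1 <- locus_count_matrix(c(m1$loci, shared), m1$samples,
                           rbind(c1, 1), "R1")
  m2 <- locus_count_matrix(c(m2$loci, shared), m2$samples,
                           rbind(c2, 2), "R2")
  coh <- prepare_cohort(list(R1 = m1, R2 = m2), unique_only = TRUE)
  expect_equal(nrow(coh$R1$counts), 10L)
  expect_equal(nrow(coh$R2$counts), 10L)
  expect_false(any(overlapsAny(coh$R1$loci, shared)))

  keep <- prepare_cohort(list(R1 = m1, R2 = m2), unique_only = FALSE)
  expect_equal(nrow(keep$R1$counts), 11L)

  # all-zero rows dropped
  z <- rbind(c1, 0)
  mz <- locus_count_matrix(c(m1$loci[1:10], shared), m1$samples, z, "R1")
  cz <- prepare_cohort(list(R1 = mz), unique_only = FALSE)
  expect_equal(nrow(cz$R1$counts), 10L)

  expect_error(prepare_cohort(list()), "empty cohort")
  bad <- locus_count_matrix(m2$loci, paste0("X", m2$samples), m2$counts, "R2")
  expect_error(prepare_cohort(list(R1 = m1, R2 = bad)), "sample set")
})

test_that("locus_coverage sums counts across samples", {
  m <- make_lcm(rbind(c(0, 0, 0), c(5, 2, 3)))
  expect_equal(locus_coverage(m, 1), 0)
  expect_equal(locus_coverage(m, 2), 10)
  set.seed(81)
  r <- matrix(rpois(50, 20), 5, 10)
  mr <- make_lcm(r)
  for (i in 1:5) expect_equal(locus_coverage(mr, i), sum(r[i, ]))
})

test_that("null matching prefers exact, then +1, then -1, flags exhaustion", {
  set.seed(91)
  res <- select_matched_null(10, c(10, 11))
  expect_equal(res$matched_coverage, 10)
  expect_false(res$exhausted)

  res <- select_matched_null(10, c(9, 11))
  expect_equal(res$matched_coverage, 11)   # higher coverage preferred

  res <- select_matched_null(10, c(9))     # no higher coverage exists
  expect_equal(res$matched_coverage, 9)

  res <- select_matched_null(10, c(7, 13))
  expect_equal(res$matched_coverage, 13)   # +3 before -3 (higher exists)
  expect_true(res$exhausted)

  expect_error(select_matched_null(10, integer(0)), "empty")

  # uniform tie-break is seed-reproducible
  pool <- rep(10, 50)
  i1 <- exrbp:::with_seed(5, select_matched_null(10, pool)$index)
  i2 <- exrbp:::with_seed(5, select_matched_null(10, pool)$index)
  expect_identical(i1, i2)
})

test_that("locus_footprint_pvalue behaves at its degenerate limits", {
  set.seed(101)
  counts <- matrix(rpois(30 * 40, 20), 30, 40)
  m <- make_lcm(counts)
  # null locus identical to the test locus: distributions nearly coincide
  # (the self-correlation of the null against the RBP adds one r = 1)
  res <- locus_footprint_pvalue(m, 3, counts[3, ])
  expect_lte(res$ks_statistic, 1 / 29 + 1e-9)
  expect_gt(res$p_value, 0.99)

  # constant locus is skipped, not a p-value
  cc <- counts; cc[5, ] <- 7
  mc <- make_lcm(cc)
  expect_message(res5 <- locus_footprint_pvalue(mc, 5, counts[1, ]),
                 "zero variance")
  expect_null(res5)
  expect_message(locus_footprint_pvalue(m, 2, rep(4, 40)), "null")
})

test_that("a planted covarying locus set yields a small locus p-value", {
  # 100 samples, 50 loci sharing a latent factor, independent null locus
  set.seed(1)
  n <- 100; L <- 50
  f <- rlnorm(n, 0, 0.8)
  counts <- t(vapply(seq_len(L), function(i)
    round(20 * f * rlnorm(n, 0, 0.5)), numeric(n)))
  m <- make_lcm(counts)
  null_counts <- round(20 * rlnorm(n, 0, sqrt(0.8^2 + 0.5^2)))
  res <- locus_footprint_pvalue(m, 1, null_counts)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$n_correlations, L - 1L)
})

test_that("rbp_footprint_test calls a planted exRBP and is deterministic", {
  cfg <- sim_config(seed = 1, n_rbps = 6, n_planted_exrbps = 2)
  sites <- simulate_sites(cfg)
  co <- simulate_cohort(cfg, sites)
  coh <- prepare_cohort(co$matrices)
  planted <- co$truth$planted_exrbps[1]
  pool <- do.call(rbind, lapply(coh[setdiff(names(coh), planted)],
                                `[[`, "counts"))
  r1 <- rbp_footprint_test(coh[[planted]], pool, seed = 3)
  expect_lt(r1$raw_p * length(coh), 0.05)
  expect_true(r1$direction_ok)
  r2 <- rbp_footprint_test(coh[[planted]], pool, seed = 3)
  expect_identical(r1$raw_p, r2$raw_p)
  expect_identical(r1$matches, r2$matches)

  tiny <- make_lcm(matrix(rpois(2 * 100, 9), 2, 100))
  expect_error(rbp_footprint_test(tiny, pool, min_loci = 10), "usable loci")
})

test_that("footprint_screen output is internally consistent", {
  cfg <- sim_config(seed = 2, n_rbps = 8, n_planted_exrbps = 2,
                    n_samples = 60)
  sites <- simulate_sites(cfg)
  co <- simulate_cohort(cfg, sites)
  coh <- prepare_cohort(co$matrices)
  scr <- footprint_screen(coh, seed = 9)
  expect_true(all(scr$calls$bonferroni_p >= scr$calls$raw_p - 1e-12))
  expect_true(all(scr$calls$bonferroni_p <= 1))
  expect_true(all(scr$calls$raw_p >= 0 & scr$calls$raw_p <= 1))
  expect_setequal(unique(scr$calls$filter) %in% names(default_filter_grid()),
                  TRUE)
  # called <=> significant and in-direction in >= 1 filter
  for (r in scr$summary$rbp) {
    d <- scr$calls[scr$calls$rbp == r, ]
    expect_equal(scr$summary$called[scr$summary$rbp == r], any(d$called))
  }
  # determinism
  scr2 <- footprint_screen(coh, seed = 9)
  expect_identical(scr$calls, scr2$calls)
})

test_that("unique-locus restriction never increases tested loci", {
  cfg <- sim_config(seed = 3, n_rbps = 6, overlap_fraction = 0.2)
  sites <- simulate_sites(cfg)
  co <- simulate_cohort(cfg, sites)
  all_loci <- prepare_cohort(co$matrices, unique_only = FALSE)
  uniq <- prepare_cohort(co$matrices, unique_only = TRUE)
  for (r in names(uniq))
    expect_lte(nrow(uniq[[r]]$counts), nrow(all_loci[[r]]$counts))
})

test_that("biotype_footprint attributes the signal to the planted biotype", {
  set.seed(111)
  n <- 80; L <- 20
  f <- rlnorm(n, 0, 0.8)
  planted <- t(vapply(seq_len(L), function(i)
    round(20 * f * rlnorm(n, 0, 0.4)), numeric(n)))
  noise1 <- matrix(round(20 * rlnorm(L * n, 0, 0.9)), L, n)
  noise2 <- matrix(round(20 * rlnorm(L * n, 0, 0.9)), L, n)
  cohort <- list(R1 = make_lcm(planted, "R1", offset = 0L),
                 R2 = make_lcm(noise1, "R2", offset = 10000L),
                 R3 = make_lcm(noise2, "R3", offset = 20000L))
  ann_gr <- c(GRanges("chrT", ranges(cohort$R1$loci),
                      gene_id = sprintf("GA%d", 1:L), biotype = "tRNA",
                      gene_name = sprintf("TA%d", 1:L)),
              GRanges("chrT", ranges(cohort$R2$loci),
                      gene_id = sprintf("GB%d", 1:L), biotype = "miRNA",
                      gene_name = sprintf("TB%d", 1:L)),
              GRanges("chrT", ranges(cohort$R3$loci),
                      gene_id = sprintf("GC%d", 1:L), biotype = "miRNA",
                      gene_name = sprintf("TC%d", 1:L)))
  ann <- annotation_set(ann_gr)
  res <- biotype_footprint(cohort, ann, min_loci = 10, seed = 4)
  called <- res[res$called, c("rbp", "biotype")]
  expect_true(any(called$rbp == "R1" & called$biotype == "tRNA"))
  expect_false(any(called$rbp != "R1"))
  # R1 has no miRNA loci, so it cannot be tested there
  expect_false(any(res$rbp == "R1" & res$biotype == "miRNA"))
})
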