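# coverage x site counting, strand accounting, biotype annotation

test_that("count_site_reads matches hand-computed depth aggregation", {
  site <- binding_site_set("R", "l", gr1("chr1", 1, 10, "+"))
  empty <- coverage_track("e", GRanges())
  expect_equal(suppressWarnings(count_site_reads(empty, site)), 0)

  # depths: [3,5] -> 3, [6,8] -> 2 (1-based)
  tr <- coverage_track("s", GRanges("chr1", IRanges::IRanges(c(3, 6), c(5, 8)),
                                    score = c(3, 2)))
  expect_equal(count_site_reads(tr, site), 3)
  expect_equal(count_site_reads(tr, site, operator = "sum"), 3 * 3 + 2 * 3)
  expect_equal(count_site_reads(tr, site, operator = "mean"), 15 / 10)

  unif <- coverage_track("u", GRanges("chr1", IRanges::IRanges(1, 10), score = 7))
  expect_equal(count_site_reads(unif, site), 7)

  # mismatched chromosome naming: zero overlap with a warning, not an error
  other <- coverage_track("o", GRanges("1", IRanges::IRanges(1, 10), score = 5))
  expect_warning(z <- count_site_reads(other, site), "no shared chromosome")
  expect_equal(z, 0)
})

test_that("counts equal the per-base brute-force oracle on random fixtures", {
  set.seed(31)
  for (rep in 1:5) {
    tr <- random_track("s")
    st <- random_sites("R")
    df <- track_to_df(tr)
    for (op in c("max", "sum", "mean")) {
      got <- count_site_reads(tr, st, operator = op)
      want <- vapply(seq_along(st$gr), function(i)
        oracle_site_stat(df, "chrT", start(st$gr)[i], end(st$gr)[i], op), 0)
      expect_equal(got, want, info = paste("operator", op))
    }
  }
})

test_that("build_rbp_matrix assembles per-sample columns", {
  st <- binding_site_set("R", "l", GRanges("chr1",
                                           IRanges::IRanges(c(1, 31, 61), c(20, 50, 80)),
                                           strand = "+"))
  tr1 <- coverage_track("s1", GRanges("chr1", IRanges::IRanges(5, 40), score = 4))
  m <- build_rbp_matrix(list(tr1), st)
  expect_s3_class(m, "LocusCountMatrix")
  expect_equal(dim(m$counts), c(3L, 1L))
  expect_equal(unname(m$counts[, 1]), count_site_reads(tr1, st))

  zero <- coverage_track("s2", GRanges())
  m2 <- suppressWarnings(build_rbp_matrix(list(tr1, zero), st))
  expect_equal(unname(m2$counts[, 2]), c(0, 0, 0))

  expect_error(build_rbp_matrix(list(tr1, tr1), st), "duplicate sample_id")

  m3 <- suppressWarnings(build_rbp_matrix(list(zero), st, drop_empty = TRUE))
  expect_equal(nrow(m3$counts), 0L)
})

test_that("build_sample_matrix zeroes non-member atoms and matches oracle", {
  a <- binding_site_set("A", "l", gr1("chr1", 1, 10, "+"))
  b <- binding_site_set("B", "l", gr1("chr1", 5, 15, "+"))
  tr <- coverage_track("s", GRanges("chr1", IRanges::IRanges(1, 15), score = 2))
  sm <- build_sample_matrix(tr, list(a, b))
  expect_equal(length(sm$atoms), 3L)
  expect_equal(unname(sm$counts[, "A"]), c(2, 2, 0))
  expect_equal(unname(sm$counts[, "B"]), c(0, 2, 2))
  # single RBP reduces to the RBP-centric row set
  sm1 <- build_sample_matrix(tr, list(a))
  expect_equal(unname(sm1$counts[, "A"]), count_site_reads(tr, a))

  set.seed(41)
  sets <- lapply(paste0("R", 1:5), random_sites)
  tr <- random_track("s")
  sm <- build_sample_matrix(tr, sets)
  df <- track_to_df(tr)
  for (k in seq_along(sm$atoms)) {
    want <- oracle_site_stat(df, "chrT", start(sm$atoms)[k], end(sm$atoms)[k])
    for (r in sm$rbp_columns) {
      expect_equal(unname(sm$counts[k, r]),
                   if (r %in% sm$members[[k]]) want else 0)
    }
  }
})

test_that("off_strand_percent spans its degenerate and mixed cases", {
  st <- binding_site_set("R", "l",
                         GRanges("chr1", IRanges::IRanges(c(1, 31), c(10, 40)),
                                 strand = c("+", "-")))
  p_cov <- coverage_track("p", GRanges("chr1", IRanges::IRanges(1, 10), score = 5))
  m_cov <- coverage_track("m", GRanges("chr1", IRanges::IRanges(31, 40), score = 3))
  # all coverage on each site's own strand
  expect_equal(off_strand_percent(p_cov, m_cov, st), 0)
  # all coverage on the opposite strand
  expect_equal(off_strand_percent(m_cov, p_cov, st), 100)

  # stranded total 8, unstranded total 10 -> 20%
  p2 <- coverage_track("p", GRanges("chr1", IRanges::IRanges(c(1, 31), c(10, 40)),
                                    score = c(5, 2)))
  m2 <- coverage_track("m", GRanges("chr1", IRanges::IRanges(31, 40), score = 3))
  # + site: stranded 5, unstranded 5; - site: stranded 3, unstranded 5
  expect_equal(off_strand_percent(p2, m2, st), 20)

  none <- coverage_track("z", GRanges())
  expect_warning(nap <- off_strand_percent(none, none, st), "undefined")
  expect_true(is.na(nap))
})

test_that("off_strand_percent stays within [0, 100] on random input", {
  set.seed(51)
  st <- random_sites("R")
  for (rep in 1:5) {
    pct <- suppressWarnings(
      off_strand_percent(random_track("p"), random_track("m"), st))
    if (!is.na(pct)) {
      expect_gte(pct, 0)
      expect_lte(pct, 100)
    }
  }
})

test_that("annotate_loci records multi-biotype overlaps and unannotated loci", {
  sites <- binding_site_set("R", "l",
                            GRanges("chr1", IRanges::IRanges(c(1, 100), c(10, 120)),
                                    strand = "+"))
  ann <- annotation_set(GRanges("chr1", IRanges::IRanges(c(5, 5), c(8, 8)),
                                gene_id = c("G1", "G1"),
                                biotype = c("pseudogene",
                                            "unprocessed_pseudogene"),
                                gene_name = c("W", "W")))
  res <- annotate_loci(sites, ann)
  expect_setequal(res$per_locus[[1]],
                  c("pseudogene", "unprocessed_pseudogene"))
  expect_equal(res$per_locus[[2]], "unannotated")
  expect_equal(res$biotype_counts[["pseudogene"]], 1L)
  expect_equal(res$biotype_counts[["unannotated"]], 1L)
})

test_that("biotype locus counts equal a brute-force overlap scan", {
  set.seed(61)
  st <- random_sites("R", n = 10L)
  astart <- sample(1900L, 12L)
  ann <- annotation_set(GRanges("chrT",
                                IRanges::IRanges(astart, astart + sample(20:80, 12, TRUE)),
                                gene_id = sprintf("G%d", 1:12),
                                biotype = sample(c("miRNA", "tRNA", "yRNA"),
                                                 12, TRUE),
                                gene_name = sprintf("N%d", 1:12)))
  res <- annotate_loci(st, ann)
  # brute force: per locus, biotypes of records sharing >= 1 base
  for (i in seq_along(st$gr)) {
    bases <- start(st$gr)[i]:end(st$gr)[i]
    hit <- vapply(seq_along(ann$gr), function(j)
      any(start(ann$gr)[j]:end(ann$gr)[j] %in% bases), TRUE)
    want <- if (any(hit)) ann$gr$biotype[hit] else "unannotated"
    expect_setequal(res$per_locus[[i]], want)
  }
})
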