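## Correlation footprinting.
##
## An RBP that carries exRNA imprints a covariation signal on the loci it
## binds: sample-to-sample variation in carrier abundance moves all of its
## loci together. The procedure tests, per RBP, whether pairwise Pearson
## correlations among its loci are stochastically larger than correlations
## against coverage-matched loci drawn from other RBPs, aggregating
## per-locus two-sample Kolmogorov-Smirnov p-values with a second,
## one-sided KS test against a mirrored null.

#' Sample/coverage filter specification
#'
#' A locus passes the filter when at least `min_samples` samples have a
#' read count of at least `min_coverage`.
#'
#' @param min_samples,min_coverage Positive integers.
#' @return An object of class `FilterSpec`.
#' @export
filter_spec <- function(min_samples, min_coverage) {
  stopifnot(min_samples >= 1, min_coverage >= 1)
  structure(list(min_samples = as.integer(min_samples),
                 min_coverage = as.integer(min_coverage)),
            class = "FilterSpec")
}

#' The six-way filter grid
#'
#' Loci present in 30/20/10 samples with coverage at least 5, and in
#' 30/20/10 samples with coverage at least 2.
#'
#' @return List of six `FilterSpec`s, named `"samples:coverage"`.
#' @export
default_filter_grid <- function() {
  grid <- list(c(30L, 5L), c(20L, 5L), c(10L, 5L),
               c(30L, 2L), c(20L, 2L), c(10L, 2L))
  out <- lapply(grid, function(g) filter_spec(g[1L], g[2L]))
  names(out) <- vapply(grid, function(g) paste0(g[1L], ":", g[2L]), "")
  out
}

#' Apply a sample/coverage filter to a count matrix
#'
#' Keeps the loci for which at least `filter$min_samples` samples have a
#' count of at least `filter$min_coverage`.
#'
#' @param m A `LocusCountMatrix`.
#' @param filter A `FilterSpec`.
#' @return The filtered `LocusCountMatrix`.
#' @export
apply_filter <- function(m, filter) {
  keep <- rowSums(m$counts >= filter$min_coverage) >= filter$min_samples
  locus_count_matrix(m$loci[keep], m$samples, m$counts[keep, , drop = FALSE],
                     m$rbp)
}

#' Prepare a cohort of per-RBP count matrices for footprinting
#'
#' Checks that all matrices share the sample set, optionally removes loci
#' present in more than one RBP's site set (unique-locus analysis), and
#' removes rows with no reads. When an RBP was assayed in both cell lines
#' the caller should supply the merged-region matrix.
#'
#' @param matrices Named list of `LocusCountMatrix`, one per RBP.
#' @param unique_only Remove loci overlapping any other RBP's loci.
#' @return Named list of filtered `LocusCountMatrix`.
#' @export
prepare_cohort <- function(matrices, unique_only = TRUE) {
  if (!length(matrices)) stop("empty cohort")
  stopifnot(all(vapply(matrices, is, TRUE, "LocusCountMatrix")))
  samp <- matrices[[1L]]$samples
  ok <- vapply(matrices, function(m) identical(m$samples, samp), TRUE)
  if (!all(ok)) stop("matrices do not share the sample set")
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, `[[`, "", "rbp")
  out <- matrices
  if (unique_only && length(matrices) > 1L) {
    for (r in names(matrices)) {
      others <- do.call(c, lapply(unname(matrices[setdiff(names(matrices), r)]),
                                  function(m) granges(m$loci)))
      keep <- !overlapsAny(matrices[[r]]$loci, others, ignore.strand = TRUE)
      m <- matrices[[r]]
      out[[r]] <- locus_count_matrix(m$loci[keep], m$samples,
                                     m$counts[keep, , drop = FALSE], m$rbp)
    }
  }
  for (r in names(out)) {
    m <- out[[r]]
    keep <- rowSums(m$counts) > 0
    out[[r]] <- locus_count_matrix(m$loci[keep], m$samples,
                                   m$counts[keep, , drop = FALSE], m$rbp)
  }
  out
}

#' Total coverage of a locus across samples
#'
#' The integer scalar used for null matching.
#'
#' @param matrix A `LocusCountMatrix`.
#' @param locus Row index (or locus key).
#' @return Summed read count across samples.
#' @export
locus_coverage <- function(matrix, locus) {
  sum(matrix$counts[locus, ])
}

#' Select a coverage-matched null locus
#'
#' Picks uniformly at random among pool loci whose total coverage equals
#' the target; failing that, among loci with coverage target + 1 (when any
#' pool locus has higher coverage than the target), else target - 1; the
#' chain extends to distance 2, 3, ... with an `exhausted` flag once the
#' matched distance exceeds 1. Ties are broken uniformly at random under
#' the caller's RNG state.
#'
#' @param target_coverage Integer target (total count across samples).
#' @param pool_coverages Integer vector of candidate coverages (loci of
#'   other RBPs).
#' @return List with `index` (into the pool), `matched_coverage`, `delta`,
#'   and `exhausted`.
#' @export
select_matched_null <- function(target_coverage, pool_coverages) {
  if (!length(pool_coverages)) stop("empty null pool")
  any_higher <- any(pool_coverages > target_coverage)
  d <- 0L
  repeat {
    if (d == 0L || any_higher) {
      hit <- which(pool_coverages == target_coverage + d)
      if (length(hit)) break
    }
    if (d > 0L) {
      hit <- which(pool_coverages == target_coverage - d)
      if (length(hit)) break
    }
    d <- d + 1L
    if (d > max(pool_coverages) + abs(target_coverage) + 1L)
      stop("null matching failed: empty fallback chain")
  }
  idx <- if (length(hit) == 1L) hit else hit[sample.int(length(hit), 1L)]
  list(index = idx, matched_coverage = pool_coverages[idx],
       delta = pool_coverages[idx] - target_coverage, exhausted = d > 1L)
}

# two-sample KS comparing two correlation vectors; NULL when not usable
ks_compare <- function(r1, r2, exact = FALSE) {
  r1 <- r1[is.finite(r1)]
  r2 <- r2[is.finite(r2)]
  if (length(r1) < 3L || length(r2) < 3L) return(NULL)
  suppressWarnings(ks.test(r1, r2, exact = exact))
}

#' Per-locus footprint p-value
#'
#' Computes Pearson correlations between the test locus and every other
#' locus of the RBP (distribution 1) and between the coverage-matched null
#' locus and every locus of the RBP (distribution 2), and compares the two
#' correlation distributions with a two-sample Kolmogorov-Smirnov test.
#' Loci with zero variance across samples, or with fewer than 3 usable
#' correlations, are skipped (returned as `NULL` with a message).
#'
#' @param matrix A `LocusCountMatrix` for the RBP.
#' @param locus Row index of the test locus.
#' @param null_counts Numeric vector: the matched null locus's counts
#'   across the same samples.
#' @param exact Passed to [stats::ks.test()] (asymptotic by default; the
#'   same convention is applied to the mirrored null, so the aggregate
#'   comparison is unaffected).
#' @return List with `ks_statistic`, `p_value`, `n_correlations`, or
#'   `NULL` when the locus is skipped.
#' @export
locus_footprint_pvalue <- function(matrix, locus, null_counts, exact = FALSE) {
  x <- matrix$counts[locus, ]
  if (var(x) == 0) {
    message("locus ", locus, " skipped: zero variance")
    return(NULL)
  }
  if (var(null_counts) == 0) {
    message("locus ", locus, " skipped: zero-variance null locus")
    return(NULL)
  }
  others <- matrix$counts[-locus, , drop = FALSE]
  vok <- apply(others, 1L, var) > 0
  others <- others[vok, , drop = FALSE]
  r_true <- suppressWarnings(as.vector(cor(x, t(others))))
  r_null <- suppressWarnings(as.vector(cor(null_counts, t(matrix$counts))))
  ks <- ks_compare(r_true, r_null, exact)
  if (is.null(ks)) {
    message("locus ", locus, " skipped: fewer than 3 usable correlations")
    return(NULL)
  }
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       n_correlations = sum(is.finite(r_true)))
}

#' Per-RBP footprint test
#'
#' For each usable locus i of the RBP, draws a coverage-matched null locus
#' n_i from the pool and computes the per-locus KS p-value p_i
#' ([locus_footprint_pvalue()]). A mirrored null is built by swapping
#' roles: q_i compares correlations of n_i against the other matched nulls
#' with correlations of the true locus i against all matched nulls. The
#' RBP-level raw p-value is a one-sided two-sample KS test of whether
#' {p_i} is stochastically smaller than {q_i}; the direction check
#' requires the median of {p_i} to be below the median of {q_i}.
#'
#' @param matrix `LocusCountMatrix` of the RBP's loci.
#' @param pool `LocusCountMatrix` (or plain counts matrix) holding the
#'   other RBPs' loci over the same samples.
#' @param seed Optional integer seed controlling null matching.
#' @param min_loci Minimum usable loci (default 10).
#' @param exact Convention for the per-locus KS tests.
#' @return List with `rbp`, `n_loci`, `ks_statistic`, `raw_p`,
#'   `direction_ok`, `p_true`, `p_null`, and the per-locus match table.
#' @export
rbp_footprint_test <- function(matrix, pool, seed = NULL, min_loci = 10L,
                               exact = FALSE) {
  pool_counts <- if (is(pool, "LocusCountMatrix")) pool$counts else as.matrix(pool)
  if (ncol(pool_counts) != ncol(matrix$counts))
    stop("pool and matrix sample sets differ")
  usable <- which(apply(matrix$counts, 1L, var) > 0)
  if (length(usable) < min_loci)
    stop("RBP ", matrix$rbp, ": only ", length(usable),
         " usable loci (need ", min_loci, ")")
  pool_ok <- which(apply(pool_counts, 1L, var) > 0)
  if (!length(pool_ok)) stop("null pool has no usable loci")
  pool_counts <- pool_counts[pool_ok, , drop = FALSE]
  pool_cov <- rowSums(pool_counts)

  with_seed(seed, {
    X <- matrix$counts[usable, , drop = FALSE]
    cov_t <- rowSums(X)
    match <- lapply(cov_t, select_matched_null, pool_coverages = pool_cov)
    ni <- vapply(match, `[[`, 0L, "index")
    N <- pool_counts[ni, , drop = FALSE]

    Ctt <- suppressWarnings(cor(t(X)))            # true x true
    Cnt <- suppressWarnings(cor(t(N), t(X)))      # null x true
    Cnn <- suppressWarnings(cor(t(N)))            # null x null
    L <- nrow(X)
    p_true <- p_null <- d_true <- rep(NA_real_, L)
    for (i in seq_len(L)) {
      ks_t <- ks_compare(Ctt[i, -i], Cnt[i, ], exact)
      ks_n <- ks_compare(Cnn[i, -i], Cnt[, i], exact)
      if (!is.null(ks_t)) {
        p_true[i] <- ks_t$p.value
        d_true[i] <- unname(ks_t$statistic)
      }
      if (!is.null(ks_n)) p_null[i] <- ks_n$p.value
    }
    ok <- is.finite(p_true) & is.finite(p_null)
    if (sum(ok) < min_loci)
      stop("RBP ", matrix$rbp, ": only ", sum(ok),
           " loci with defined p-values (need ", min_loci, ")")
    agg <- suppressWarnings(
      ks.test(p_true[ok], p_null[ok], alternative = "greater"))
    list(rbp = matrix$rbp,
         n_loci = sum(ok),
         ks_statistic = unname(agg$statistic),
         raw_p = agg$p.value,
         direction_ok = median(p_true[ok]) < median(p_null[ok]),
         p_true = p_true[ok], p_null = p_null[ok],
         matches = data.frame(locus = usable[ok],
                              target_coverage = cov_t[ok],
                              matched_coverage = vapply(match, `[[`, 0,
                                                        "matched_coverage")[ok],
                              exhausted = vapply(match, `[[`, TRUE,
                                                 "exhausted")[ok],
                              locus_D = d_true[ok], locus_p = p_true[ok]))
  })
}

#' Footprint screen over the filter grid
#'
#' Runs [rbp_footprint_test()] for every RBP under each filter in the grid
#' (default [default_filter_grid()]). Within one (cohort, filter) run,
#' Bonferroni multiplies each raw p-value by the number of RBPs tested in
#' that run (capped at 1). An RBP is called when it is significant, with
#' the correct direction, in at least one filter set; the filter with the
#' smallest adjusted p is reported as best.
#'
#' @param cohort Named list of `LocusCountMatrix` from [prepare_cohort()].
#' @param alpha Significance level on the Bonferroni-adjusted p (0.05).
#' @param filters List of `FilterSpec`s.
#' @param min_loci Minimum usable loci per test.
#' @param seed Optional integer seed (null matching).
#' @param cohort_label Label written into the output table.
#' @return List with `calls` (one row per RBP x filter tested: rbp,
#'   cohort, filter, n_loci, D, raw_p, bonferroni_p, direction_ok,
#'   called) and `summary` (one row per RBP: called, best filter,
#'   best adjusted p). Empty with a warning when nothing is testable.
#' @export
footprint_screen <- function(cohort, alpha = 0.05,
                             filters = default_filter_grid(),
                             min_loci = 10L, seed = NULL,
                             cohort_label = "cohort") {
  stopifnot(length(cohort) >= 2L)
  if (is.null(names(filters)))
    names(filters) <- vapply(filters, function(f)
      paste0(f$min_samples, ":", f$min_coverage), "")
  rows <- list()
  for (fname in names(filters)) {
    f <- filters[[fname]]
    filtered <- lapply(cohort, apply_filter, filter = f)
    usable_n <- vapply(filtered, function(m)
      sum(apply(m$counts, 1L, var) > 0), 0L)
    testable <- names(filtered)[usable_n >= min_loci]
    if (!length(testable)) next
    n_tested <- length(testable)
    for (r in testable) {
      pool <- do.call(rbind, lapply(unname(filtered[setdiff(names(filtered), r)]),
                                    `[[`, "counts"))
      sub_seed <- if (is.null(seed)) NULL else
        (seed + 7L * match(fname, names(filters)) +
           131L * match(r, names(cohort))) %% .Machine$integer.max
      res <- tryCatch(
        rbp_footprint_test(filtered[[r]], pool, seed = sub_seed,
                           min_loci = min_loci),
        error = function(e) NULL)
      if (is.null(res)) next
      bonf <- min(1, res$raw_p * n_tested)
      rows[[length(rows) + 1L]] <- data.frame(
        rbp = r, cohort = cohort_label, filter = fname,
        n_loci = res$n_loci, D = res$ks_statistic, raw_p = res$raw_p,
        bonferroni_p = bonf, direction_ok = res$direction_ok,
        called = bonf < alpha && res$direction_ok)
    }
  }
  if (!length(rows)) {
    warning("no RBP testable under any filter")
    empty <- data.frame(rbp = character(), cohort = character(),
                        filter = character(), n_loci = integer(),
                        D = numeric(), raw_p = numeric(),
                        bonferroni_p = numeric(), direction_ok = logical(),
                        called = logical())
    return(list(calls = empty,
                summary = data.frame(rbp = character(), called = logical(),
                                     best_filter = character(),
                                     best_bonferroni_p = numeric())))
  }
  calls <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(calls, calls$rbp), function(d) {
    b <- which.min(d$bonferroni_p)
    data.frame(rbp = d$rbp[1L], called = any(d$called),
               best_filter = d$filter[b], best_bonferroni_p = d$bonferroni_p[b])
  }))
  rownames(summ) <- NULL
  list(calls = calls, summary = summ)
}

#' Biotype-restricted footprint tests
#'
#' Subsets each RBP's loci to those overlapping a biotype's annotation
#' records and re-runs the footprint procedure on the subset (the
#' coverage-matched null pool remains the other RBPs' full locus sets, so
#' matching stays non-degenerate for rare biotypes). RBP/biotype
#' pairs with too few loci are skipped with a reason. Bonferroni spans the
#' RBPs tested within one biotype.
#'
#' @param cohort Named list of `LocusCountMatrix` (prepared).
#' @param ann An `AnnotationSet`.
#' @param biotypes Biotypes to test (default: all in `ann`).
#' @param alpha Adjusted-p threshold.
#' @param min_loci Minimum usable loci.
#' @param seed Optional seed.
#' @return Data frame: rbp, biotype, n_loci, D, raw_p, bonferroni_p,
#'   direction_ok, called.
#' @export
biotype_footprint <- function(cohort, ann, biotypes = NULL, alpha = 0.05,
                              min_loci = 10L, seed = NULL) {
  stopifnot(is(ann, "AnnotationSet"))
  biotypes <- biotypes %||% sort(unique(ann$gr$biotype))
  rows <- list()
  for (b in biotypes) {
    bg <- ann$gr[ann$gr$biotype == b]
    sub <- lapply(cohort, function(m) {
      keep <- overlapsAny(m$loci, bg, ignore.strand = TRUE)
      locus_count_matrix(m$loci[keep], m$samples,
                         m$counts[keep, , drop = FALSE], m$rbp)
    })
    usable_n <- vapply(sub, function(m)
      sum(apply(m$counts, 1L, var) > 0), 0L)
    testable <- names(sub)[usable_n >= min_loci]
    if (!length(testable)) next
    for (r in testable) {
      pool <- do.call(rbind, lapply(unname(cohort[setdiff(names(cohort), r)]),
                                    `[[`, "counts"))
      if (is.null(pool) || !nrow(pool)) next
      sub_seed <- if (is.null(seed)) NULL else
        (seed + 17L * match(b, biotypes) + 131L * match(r, names(cohort))) %%
          .Machine$integer.max
      res <- tryCatch(
        rbp_footprint_test(sub[[r]], pool, seed = sub_seed,
                           min_loci = min_loci),
        error = function(e) NULL)
      if (is.null(res)) next
      bonf <- min(1, res$raw_p * length(testable))
      rows[[length(rows) + 1L]] <- data.frame(
        rbp = r, biotype = b, n_loci = res$n_loci, D = res$ks_statistic,
        raw_p = res$raw_p, bonferroni_p = bonf,
        direction_ok = res$direction_ok,
        called = bonf < alpha && res$direction_ok)
    }
  }
  if (!length(rows))
    return(data.frame(rbp = character(), biotype = character(),
                      n_loci = integer(), D = numeric(), raw_p = numeric(),
                      bonferroni_p = numeric(), direction_ok = logical(),
                      called = logical()))
  do.call(rbind, rows)
}
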