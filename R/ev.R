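## Small-cohort EV analysis.
##
## With only four extracellular-vesicle samples, the correlation footprint
## cannot be estimated; instead, cross-sample consistency of an RBP's
## locus profile is scored by the coefficient of variation of pairwise
## between-sample differences and tested against shuffled count matrices.

#' Filter RBPs eligible for the EV permutation test
#'
#' Keeps, per RBP, the loci with a nonzero count in at least
#' `min_nonzero_samples` samples, and keeps the RBPs retaining at least
#' `min_loci` such loci.
#'
#' @param matrices Named list of `LocusCountMatrix` (or plain count
#'   matrices) over the same samples.
#' @param min_loci Minimum qualifying loci per RBP (default 15).
#' @param min_nonzero_samples Minimum samples with a nonzero count
#'   (default 2).
#' @return Named list of filtered count matrices for the eligible RBPs
#'   (possibly empty).
#' @export
filter_ev_rbps <- function(matrices, min_loci = 15L, min_nonzero_samples = 2L) {
  get_counts <- function(m) if (is(m, "LocusCountMatrix")) m$counts else as.matrix(m)
  out <- list()
  for (r in names(matrices)) {
    counts <- get_counts(matrices[[r]])
    keep <- rowSums(counts > 0) >= min_nonzero_samples
    if (sum(keep) >= min_loci)
      out[[r]] <- counts[keep, , drop = FALSE]
  }
  out
}

#' Pooled coefficient of variation of pairwise sample differences
#'
#' Forms the absolute difference `|x(l, s) - x(l, t)|` for every locus
#' `l` and every unordered sample pair `(s, t)` (4 samples give 6 pairs,
#' so L loci pool 6 L values) and returns `100 * sd / mean` over the
#' pooled values. A pooled mean of zero (all samples identical at every
#' locus, i.e. perfect consistency) is defined as 0 with a warning.
#'
#' @param matrix Numeric loci x samples matrix (at least 2 of each).
#' @return The CV, in percent.
#' @export
cv_statistic <- function(matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) >= 2L, ncol(matrix) >= 2L)
  pr <- combn(ncol(matrix), 2L)
  d <- abs(matrix[, pr[1L, ], drop = FALSE] - matrix[, pr[2L, ], drop = FALSE])
  m <- mean(d)
  if (m == 0) {
    warning("all pairwise differences are zero; CV defined as 0")
    return(0)
  }
  100 * sd(as.vector(d)) / m
}

#' Permutation p-value for cross-sample consistency
#'
#' The null distribution is generated by shuffling all cells of the count
#' matrix (destroying both locus identity and sample assignment while
#' preserving the pooled counts) and recomputing [cv_statistic()];
#' `p = (1 + #\{CV_null <= CV_obs\}) / (n_perm + 1)` (lower tail:
#' consistent RBPs disperse their pairwise differences less, relative to
#' the mean, than shuffled ones). The smallest attainable p is
#' `1 / (n_perm + 1)`.
#'
#' @param matrix Numeric loci x samples count matrix (filtered as in
#'   [filter_ev_rbps()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param alpha Significance level (default 0.05).
#' @return List with `cv_observed`, `p_value`, `n_perm`, `significant`.
#' @export
permutation_pvalue <- function(matrix, n_perm = 1000L, seed = NULL,
                               alpha = 0.05) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  matrix <- as.matrix(matrix)
  obs <- cv_statistic(matrix)
  with_seed(seed, {
    L <- nrow(matrix); S <- ncol(matrix)
    nulls <- vapply(seq_len(n_perm), function(i)
      suppressWarnings(cv_statistic(base::matrix(sample(matrix), L, S))),
      0)
    p <- (1 + sum(nulls <= obs)) / (n_perm + 1)
    list(cv_observed = obs, p_value = p, n_perm = as.integer(n_perm),
         significant = p < alpha)
  })
}

#' Run the EV permutation test over a cohort, with randomized controls
#'
#' Convenience driver: filters eligible RBPs, tests each, and (optionally)
#' repeats the test on size-matched random locus sets drawn from the other
#' RBPs' eligible loci.
#'
#' @param matrices Named list of `LocusCountMatrix`/matrices.
#' @param n_perm Permutations per test.
#' @param seed Integer seed (controls permutations and control draws).
#' @param alpha Significance level.
#' @param randomized_controls Also test randomized locus sets.
#' @return List with `true` and (optionally) `random`: data frames of
#'   rbp, n_loci, cv_observed, p_value, significant, randomized.
#' @export
ev_cohort_test <- function(matrices, n_perm = 1000L, seed = 1L, alpha = 0.05,
                           randomized_controls = TRUE) {
  eligible <- filter_ev_rbps(matrices)
  if (!length(eligible))
    return(list(true = data.frame(), random = data.frame()))
  run <- function(mats, randomized) {
    rows <- lapply(names(mats), function(r) {
      res <- permutation_pvalue(mats[[r]], n_perm = n_perm,
                                seed = seed + 1000L * match(r, names(mats)) +
                                  if (randomized) 499L else 0L,
                                alpha = alpha)
      data.frame(rbp = r, n_loci = nrow(mats[[r]]),
                 cv_observed = res$cv_observed, p_value = res$p_value,
                 significant = res$significant, randomized = randomized)
    })
    do.call(rbind, rows)
  }
  out <- list(true = run(eligible, FALSE))
  if (randomized_controls) {
    all_counts <- do.call(rbind, unname(eligible))
    owner <- rep(names(eligible), vapply(eligible, nrow, 0L))
    random_sets <- with_seed(seed, {
      sets <- list()
      for (r in names(eligible)) {
        pool <- which(owner != r)
        take <- sample(pool, min(nrow(eligible[[r]]), length(pool)))
        sets[[r]] <- all_counts[take, , drop = FALSE]
      }
      sets
    })
    out$random <- run(random_sets, TRUE)
  }
  out
}

#' Cohort-level false-discovery estimate from randomized controls
#'
#' `fdr_percent = 100 * n_sig_random / n_sig_true` (e.g. 15 significant
#' randomized sets against 50 significant true sets estimate a 30% FDR),
#' plus a two-sample Kolmogorov-Smirnov comparison of the two p-value
#' distributions.
#'
#' @param true_results,random_results Data frames with `p_value` and
#'   `significant` columns ([ev_cohort_test()] output).
#' @param alpha Significance level used for the counts.
#' @return List with `n_sig_true`, `n_sig_random`, `fdr_percent` (`NA`
#'   with a warning when no true set is significant) and `ks_p`.
#' @export
cohort_fdr <- function(true_results, random_results, alpha = 0.05) {
  n_true <- sum(true_results$p_value < alpha)
  n_rand <- sum(random_results$p_value < alpha)
  fdr <- if (n_true == 0) {
    warning("no significant true sets; FDR undefined")
    NA_real_
  } else 100 * n_rand / n_true
  ks <- suppressWarnings(
    ks.test(true_results$p_value, random_results$p_value))
  list(n_sig_true = n_true, n_sig_random = n_rand, fdr_percent = fdr,
       ks_p = ks$p.value)
}
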