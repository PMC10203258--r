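## Cargo-type (CT) enrichment of RBPs.
##
## Deconvolved exRNA carrier profiles assign per-locus average per-base
## coverage to each cargo type (CT1 low-density vesicles, CT2 lipoprotein
## particles, CT3A/B/C ribonucleoprotein-associated, CT4 high-density
## vesicles, or density-gradient fraction classes). The enrichment score
## of an RBP in a CT is the mean per-base coverage of its loci in that CT
## divided by the unweighted grand mean over CTs, so each row of the
## enrichment table averages to exactly 1.

#' Cargo-type enrichment scores for one RBP
#'
#' `score(CT) = mean over loci of per-base coverage in CT / grand mean`,
#' where the grand mean is the unweighted mean over CTs of the per-CT
#' means (equal CT weights; this makes the row average exactly 1).
#'
#' @param profiles Numeric matrix, loci x CTs, of average per-base
#'   coverage (read count divided by locus length, averaged over the CT's
#'   profiles). Column names are the CT labels.
#' @param rbp_loci Optional row subset (indices or logical) restricting to
#'   the RBP's loci.
#' @return Named numeric vector of per-CT scores, or `NULL` (with a
#'   warning) when the grand mean is zero.
#' @export
ct_enrichment <- function(profiles, rbp_loci = NULL) {
  profiles <- as.matrix(profiles)
  if (!is.null(rbp_loci)) profiles <- profiles[rbp_loci, , drop = FALSE]
  stopifnot(nrow(profiles) >= 1L, ncol(profiles) >= 2L, all(profiles >= 0))
  ct_means <- colMeans(profiles)
  grand <- mean(ct_means)
  if (grand == 0) {
    warning("zero grand-mean coverage; row dropped")
    return(NULL)
  }
  ct_means / grand
}

#' Enrichment table over many RBPs
#'
#' Applies [ct_enrichment()] to each RBP's profile matrix; rows with zero
#' grand-mean coverage are dropped with a warning.
#'
#' @param profiles Named list of loci x CT coverage matrices, one per RBP
#'   (shared CT columns).
#' @return Matrix, RBPs x CTs, each row averaging to 1.
#' @export
enrichment_table <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  rows <- lapply(profiles, ct_enrichment)
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(profiles)[keep]
  out
}

#' Threshold an enrichment table into per-RBP CT sets
#'
#' A cell is enriched when its score is at least `threshold` (default 1.4,
#' chosen in the source analysis just above the 75th percentile of all
#' scores, 1.34; see [enrichment_percentile()]). Raising the threshold
#' never adds a CT to any set.
#'
#' @param table RBP x CT score matrix ([enrichment_table()]).
#' @param threshold Enrichment cutoff (non-strict `>=`).
#' @return List with `sets` (named list of enriched-CT character vectors
#'   per RBP) and `set_counts` (data frame counting RBPs per distinct CT
#'   set, upset-style).
#' @export
enriched_cts <- function(table, threshold = 1.4) {
  table <- as.matrix(table)
  sets <- apply(table, 1L, function(row)
    colnames(table)[row >= threshold], simplify = FALSE)
  key <- vapply(sets, function(s)
    if (length(s)) paste(sort(s), collapse = "+") else "(none)", "")
  tab <- table(key)
  set_counts <- data.frame(ct_set = names(tab),
                           n_rbps = as.integer(tab),
                           row.names = NULL)
  set_counts <- set_counts[order(-set_counts$n_rbps, set_counts$ct_set), ]
  rownames(set_counts) <- NULL
  list(sets = sets, set_counts = set_counts)
}

#' 75th-percentile utility for enrichment scores
#'
#' @param table RBP x CT score matrix.
#' @param probs Quantile (default 0.75).
#' @return The quantile of all scores.
#' @export
enrichment_percentile <- function(table, probs = 0.75) {
  unname(quantile(as.vector(as.matrix(table)), probs))
}

#' Cargo-type to density-gradient fraction mapping
#'
#' Two mappings between the six deconvolved cargo types and the
#' C-DGUC fraction classes are reported by the source analysis and they
#' disagree for CT1/CT2: the `"results"` mapping pairs fractions 1-3 with
#' CT4, 4-7 with CT1, 9-12 with CT2; the `"methods"` variant pairs CT1
#' with fractions 9-12 and CT2 with 4-7. Unfractionated material maps to
#' CT3 (A, B and C) in both.
#'
#' @param which `"results"` (default) or `"methods"`.
#' @return Named character vector, CT label -> fraction class.
#' @export
ct_fraction_mapping <- function(which = c("results", "methods")) {
  which <- match.arg(which)
  base <- c(CT3 = "unfractionated", CT3A = "unfractionated",
            CT3B = "unfractionated", CT3C = "unfractionated",
            CT4 = "fractions_1_3")
  if (which == "results")
    c(base, CT1 = "fractions_4_7", CT2 = "fractions_9_12")
  else
    c(base, CT1 = "fractions_9_12", CT2 = "fractions_4_7")
}

#' Concordance between deconvolved-CT and fraction-class assignments
#'
#' An RBP is consistent when at least one of its enriched CTs maps to one
#' of its enriched fraction classes.
#'
#' @param ct_sets Named list of enriched CT sets per RBP
#'   ([enriched_cts()]`$sets` on the deconvolved profiles).
#' @param fraction_sets Named list of enriched fraction-class sets per RBP
#'   (same thresholding on the fraction profiles).
#' @param mapping CT -> fraction class map ([ct_fraction_mapping()]).
#' @return Character vector of consistent RBPs (intersection of the two
#'   tables' RBP universes).
#' @export
fraction_consistency <- function(ct_sets, fraction_sets,
                                 mapping = ct_fraction_mapping("results")) {
  rbps <- intersect(names(ct_sets), names(fraction_sets))
  used_cts <- unique(unlist(ct_sets[rbps]))
  missing <- setdiff(used_cts, names(mapping))
  if (length(missing))
    stop("mapping lacks CT(s): ", paste(missing, collapse = ", "))
  ok <- vapply(rbps, function(r) {
    mapped <- unname(mapping[ct_sets[[r]]])
    length(intersect(mapped, fraction_sets[[r]])) > 0L
  }, TRUE)
  rbps[ok]
}

#' Biotype fraction of the genome bound per cargo type, with tests
#'
#' Per study, a binding-site locus is expressed when at least one sample
#' carries `expressed_cutoff` reads; it is expressed within a CT when its
#' estimated CT count reaches `ct_cutoff`. For each biotype and CT the
#' fraction is the number of unique bases of genes (of that biotype)
#' overlapping at least one locus passing both cutoffs, divided by the
#' unique bases of all genes of the biotype (overlap is
#' non-strand-specific). A Kruskal-Wallis omnibus test across CTs is run
#' per biotype over the per-study fractions; where the omnibus p is below
#' `alpha`, pairwise Wilcoxon rank-sum tests with Holm adjustment follow.
#'
#' @param studies List of studies; each a list with `loci` (`GRanges` of
#'   binding sites), `max_reads` (per-locus maximum sample read count) and
#'   `ct_counts` (loci x CT matrix of estimated counts, shared CT
#'   columns).
#' @param ann An `AnnotationSet` of gene records with biotypes.
#' @param expressed_cutoff Minimum per-sample read count (default 5).
#' @param ct_cutoff Minimum estimated count within a CT (default 2).
#' @param alpha Omnibus threshold gating the pairwise tests.
#' @return List with `fractions` (study, biotype, ct, fraction),
#'   `omnibus` (biotype, kw_p) and `pairwise` (biotype, ct_a, ct_b,
#'   holm_p; empty when no omnibus test is significant).
#' @export
biotype_ct_fraction <- function(studies, ann, expressed_cutoff = 5,
                                ct_cutoff = 2, alpha = 0.05) {
  stopifnot(is(ann, "AnnotationSet"), length(studies) >= 1L)
  cts <- colnames(studies[[1L]]$ct_counts)
  biotypes <- sort(unique(ann$gr$biotype))
  rows <- list()
  for (si in seq_along(studies)) {
    st <- studies[[si]]
    stopifnot(identical(colnames(st$ct_counts), cts),
              length(st$max_reads) == length(st$loci))
    expressed <- st$max_reads >= expressed_cutoff
    for (ct in cts) {
      pass <- expressed & st$ct_counts[, ct] >= ct_cutoff
      passing_loci <- st$loci[pass]
      for (b in biotypes) {
        genes <- ann$gr[ann$gr$biotype == b]
        denom <- sum(width(reduce(genes, ignore.strand = TRUE)))
        bound <- genes[overlapsAny(genes, passing_loci, ignore.strand = TRUE)]
        num <- sum(width(reduce(bound, ignore.strand = TRUE)))
        rows[[length(rows) + 1L]] <- data.frame(
          study = si, biotype = b, ct = ct,
          fraction = if (denom > 0) num / denom else NA_real_)
      }
    }
  }
  fr <- do.call(rbind, rows)
  omnibus <- do.call(rbind, lapply(split(fr, fr$biotype), function(d) {
    p <- if (length(unique(d$ct)) < 2L || anyNA(d$fraction)) NA_real_
    else if (var(d$fraction) == 0) 1  # no variation, no association
    else kruskal.test(d$fraction, factor(d$ct))$p.value
    data.frame(biotype = d$biotype[1L], kw_p = p)
  }))
  rownames(omnibus) <- NULL
  pw <- list()
  for (b in omnibus$biotype[!is.na(omnibus$kw_p) & omnibus$kw_p < alpha]) {
    d <- fr[fr$biotype == b, ]
    pt <- suppressWarnings(
      pairwise.wilcox.test(d$fraction, factor(d$ct), p.adjust.method = "holm"))
    m <- pt$p.value
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      if (!is.na(m[i, j]))
        pw[[length(pw) + 1L]] <- data.frame(
          biotype = b, ct_a = rownames(m)[i], ct_b = colnames(m)[j],
          holm_p = m[i, j])
  }
  pairwise <- if (length(pw)) do.call(rbind, pw) else
    data.frame(biotype = character(), ct_a = character(),
               ct_b = character(), holm_p = numeric())
  list(fractions = fr, omnibus = omnibus, pairwise = pairwise)
}
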