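## Coverage x binding-site intersection: count matrices, strand accounting,
## biotype annotation.
##
## The read-count proxy for a region is an aggregation of per-base depth
## inside it; exRNA fragments are shorter than reads, so stacked identical
## fragments produce a depth equal to the read count and the per-base
## maximum recovers it. The operator is configurable (max | sum | mean),
## max being the default.

# Per-site depth statistic. cov_gr: GRanges with score; sites_gr: GRanges.
# Returns one value per site, 0 where there is no overlap.
site_depth_stat <- function(cov_gr, sites_gr, operator = "max") {
  operator <- match.arg(operator, c("max", "sum", "mean"))
  out <- numeric(length(sites_gr))
  if (!length(sites_gr)) return(out)
  if (!length(cov_gr)) return(out)
  shared <- intersect(unique(as.character(seqnames(cov_gr))),
                      unique(as.character(seqnames(sites_gr))))
  if (!length(shared)) {
    warning("no shared chromosome names between track and sites; ",
            "all counts are zero")
    return(out)
  }
  # common coordinate universe so Views never run past the Rle
  ends <- c(end(cov_gr), end(sites_gr))
  chrs <- c(as.character(seqnames(cov_gr)), as.character(seqnames(sites_gr)))
  lens <- vapply(split(ends, chrs), max, 0)
  cov_gr2 <- GRanges(as.character(seqnames(cov_gr)), ranges(cov_gr),
                     seqlengths = lens)
  covr <- coverage(cov_gr2, weight = cov_gr$score)
  schr <- as.character(seqnames(sites_gr))
  for (chr in intersect(names(covr), unique(schr))) {
    i <- which(schr == chr)
    v <- Views(covr[[chr]], start(sites_gr)[i], end(sites_gr)[i])
    out[i] <- switch(operator,
                     max = viewMaxs(v),
                     sum = viewSums(v),
                     mean = viewMeans(v))
  }
  out
}

#' Per-site read counts from a coverage track
#'
#' For each binding site, aggregates the per-base depth inside the site
#' (default: maximum) as a read-count proxy; sites with no overlapping
#' coverage get 0. With `stranded = TRUE` only coverage intervals on the
#' site's own strand contribute, which requires a track whose intervals
#' carry strand (see [strand_split_track()]).
#'
#' @param track A `CoverageTrack`.
#' @param sites A `BindingSiteSet`.
#' @param operator Aggregation over bases: `"max"` (default), `"sum"`, or
#'   `"mean"`.
#' @param stranded Restrict coverage to the site's strand.
#' @return Numeric vector, one value per site (site order preserved).
#' @export
count_site_reads <- function(track, sites, operator = "max", stranded = FALSE) {
  stopifnot(is(track, "CoverageTrack"), is(sites, "BindingSiteSet"))
  if (!stranded)
    return(site_depth_stat(track$gr, sites$gr, operator))
  out <- numeric(length(sites$gr))
  for (s in c("+", "-")) {
    i <- which(as.character(strand(sites$gr)) == s)
    if (!length(i)) next
    covs <- track$gr[as.character(strand(track$gr)) == s]
    out[i] <- site_depth_stat(covs, sites$gr[i], operator)
  }
  out
}

#' Combine strand-split coverage into one stranded track
#'
#' @param track_plus,track_minus `CoverageTrack`s holding the
#'   positive-strand and negative-strand coverage of one sample.
#' @return A `CoverageTrack` whose intervals carry strand.
#' @export
strand_split_track <- function(track_plus, track_minus) {
  stopifnot(is(track_plus, "CoverageTrack"), is(track_minus, "CoverageTrack"))
  gp <- track_plus$gr; strand(gp) <- "+"
  gm <- track_minus$gr; strand(gm) <- "-"
  gr <- sort(c(gp, gm), ignore.strand = TRUE)
  structure(list(sample_id = track_plus$sample_id, gr = gr),
            class = "CoverageTrack")
}

#' Locus-by-sample count matrix
#'
#' @param loci `GRanges` of loci (unique).
#' @param samples Character vector of sample ids.
#' @param counts Numeric matrix, loci x samples, non-negative.
#' @param rbp RBP symbol the loci belong to (or `"atoms"`).
#' @return An object of class `LocusCountMatrix`.
#' @export
locus_count_matrix <- function(loci, samples, counts, rbp) {
  counts <- as.matrix(counts)
  stopifnot(is(loci, "GRanges"), nrow(counts) == length(loci),
            ncol(counts) == length(samples), all(counts >= 0))
  if (anyDuplicated(samples)) stop("duplicate sample_id")
  key <- if (length(loci)) paste0(as.character(seqnames(loci)), ":",
                                  start(loci) - 1L, "-", end(loci),
                                  "(", as.character(strand(loci)), ")")
         else character(0)
  if (anyDuplicated(key)) stop("duplicate loci")
  dimnames(counts) <- list(key, samples)
  structure(list(loci = loci, samples = as.character(samples),
                 counts = counts, rbp = rbp),
            class = "LocusCountMatrix")
}

#' @export
print.LocusCountMatrix <- function(x, ...) {
  cat("LocusCountMatrix [", x$rbp, "]: ", nrow(x$counts), " loci x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' RBP-centric count matrix across samples
#'
#' Column `s` holds [count_site_reads()] of track `s` against the sites;
#' loci keep the site order. Optionally drops loci with zero counts in
#' every sample (`drop_empty`), as done before cohort statistics.
#'
#' @param tracks List of `CoverageTrack`s (distinct `sample_id`s).
#' @param sites A `BindingSiteSet`.
#' @inheritParams count_site_reads
#' @param drop_empty Drop all-zero rows.
#' @return A `LocusCountMatrix`.
#' @export
build_rbp_matrix <- function(tracks, sites, operator = "max",
                             stranded = FALSE, drop_empty = FALSE) {
  stopifnot(length(tracks) >= 1L)
  ids <- vapply(tracks, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample_id among tracks")
  counts <- vapply(tracks, count_site_reads, numeric(length(sites$gr)),
                   sites = sites, operator = operator, stranded = stranded)
  counts <- matrix(counts, nrow = length(sites$gr), ncol = length(tracks))
  m <- locus_count_matrix(sites$gr, ids, counts, sites$rbp)
  if (drop_empty) {
    keep <- rowSums(m$counts) > 0
    m <- locus_count_matrix(m$loci[keep], m$samples,
                            m$counts[keep, , drop = FALSE], m$rbp)
  }
  m
}

#' Sample-centric atom-by-RBP matrix
#'
#' Rows are the atomic regions of [partition_union()]; the entry for
#' (atom, RBP) is the read-count proxy of the sample's coverage inside the
#' atom when the RBP is a member of the atom, else 0.
#'
#' @param track A `CoverageTrack` (one sample).
#' @param sets List of `BindingSiteSet`s.
#' @inheritParams count_site_reads
#' @return An object of class `SampleRBPMatrix`: list with `atoms`
#'   (`GRanges`), `members` (list), `rbp_columns`, `counts`.
#' @export
build_sample_matrix <- function(track, sets, operator = "max") {
  stopifnot(length(sets) >= 1L)
  part <- partition_union(sets)
  rbps <- sort(unique(vapply(sets, `[[`, "", "rbp")))
  depth <- site_depth_stat(track$gr, part$atoms, operator)
  counts <- matrix(0, nrow = length(part$atoms), ncol = length(rbps),
                   dimnames = list(NULL, rbps))
  for (j in seq_along(rbps)) {
    in_j <- vapply(part$members, function(m) rbps[j] %in% m, TRUE)
    counts[in_j, j] <- depth[in_j]
  }
  structure(list(atoms = part$atoms, members = part$members,
                 rbp_columns = rbps, counts = counts),
            class = "SampleRBPMatrix")
}

#' Off-strand coverage percentage
#'
#' Compares stranded-matched and unstranded read-count totals over a site
#' set for one sample split into plus/minus coverage tracks:
#' `100 * (unstranded - stranded) / unstranded`. Returns `NA` with a
#' warning when the unstranded total is zero. Callers average the
#' percentage across samples.
#'
#' @param track_plus,track_minus Strand-split `CoverageTrack`s of one
#'   sample.
#' @param sites A `BindingSiteSet`.
#' @param operator Read-count proxy operator.
#' @return A percentage in `[0, 100]`, or `NA`.
#' @export
off_strand_percent <- function(track_plus, track_minus, sites,
                               operator = "max") {
  both <- strand_split_track(track_plus, track_minus)
  stranded_counts <- count_site_reads(both, sites, operator, stranded = TRUE)
  un <- both
  strand(un$gr) <- "*"
  unstranded_counts <- count_site_reads(un, sites, operator)
  tot_u <- sum(unstranded_counts)
  if (tot_u == 0) {
    warning("unstranded total is zero; off-strand percentage undefined")
    return(NA_real_)
  }
  100 * (tot_u - sum(stranded_counts)) / tot_u
}

#' Annotate loci with overlapping biotypes
#'
#' Each locus receives the biotypes of all overlapping annotation records
#' (kept as a multiset: one entry per record, so a region annotated by
#' several records contributes each of their biotypes); loci overlapping
#' nothing are labelled `"unannotated"`. Overlap is non-strand-specific.
#' The aggregate counts one locus once per distinct biotype it carries.
#'
#' @param sites A `BindingSiteSet` (or `GRanges`).
#' @param ann An `AnnotationSet`.
#' @return List with `per_locus` (list of character vectors, one per
#'   locus) and `biotype_counts` (named integer vector).
#' @export
annotate_loci <- function(sites, ann) {
  gr <- if (is(sites, "BindingSiteSet")) sites$gr else sites
  stopifnot(is(ann, "AnnotationSet"))
  per_locus <- rep(list("unannotated"), length(gr))
  hits <- findOverlaps(gr, ann$gr, ignore.strand = TRUE)
  got <- split(ann$gr$biotype[subjectHits(hits)], queryHits(hits))
  per_locus[as.integer(names(got))] <- got
  distinct <- lapply(per_locus, unique)
  counts <- table(unlist(distinct))
  list(per_locus = per_locus,
       biotype_counts = stats::setNames(as.integer(counts), names(counts)))
}
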