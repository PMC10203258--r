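# Brute-force per-base oracles and small fixture builders, used across the
# suite to check the interval machinery independently of GenomicRanges.
# All oracles work on 1-based inclusive coordinates over a small universe.

library(GenomicRanges)

# GRanges shorthand (1-based inclusive starts/ends)
gr1 <- function(chrom, start, end, strand = "*") {
  GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

# per-base depth vector for one chromosome from a coverage data frame
# (chrom, start1, end1, depth); universe 1..len
oracle_depth_vector <- function(cov_df, chrom, len) {
  v <- numeric(len)
  d <- cov_df[cov_df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    v[d$start1[i]:d$end1[i]] <- v[d$start1[i]:d$end1[i]] + d$depth[i]
  }
  v
}

# read-count proxy for one site by explicit per-base scan
oracle_site_stat <- function(cov_df, chrom, start1, end1, op = "max",
                             universe = 10000L) {
  v <- oracle_depth_vector(cov_df, chrom, universe)[start1:end1]
  switch(op, max = max(v), sum = sum(v), mean = mean(v))
}

track_to_df <- function(track) {
  g <- track$gr
  data.frame(chrom = as.character(seqnames(g)), start1 = start(g),
             end1 = end(g), depth = g$score)
}

# per-base membership oracle: which RBPs cover each base
oracle_memberships <- function(sets, chrom, universe = 10000L) {
  m <- matrix(FALSE, universe, length(sets),
              dimnames = list(NULL, vapply(sets, `[[`, "", "rbp")))
  for (s in sets) {
    g <- s$gr[as.character(seqnames(s$gr)) == chrom]
    for (i in seq_along(g)) m[start(g)[i]:end(g)[i], s$rbp] <- TRUE
  }
  m
}

# atoms from the membership oracle: runs of constant nonempty membership
oracle_atoms <- function(sets, chrom, universe = 10000L) {
  m <- oracle_memberships(sets, chrom, universe)
  key <- apply(m, 1L, function(r) paste(colnames(m)[r], collapse = ";"))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- nzchar(r$values)
  data.frame(start1 = starts[keep], end1 = ends[keep],
             members = r$values[keep])
}

# strand-aware per-base union oracle for merge: returns covered base count
oracle_union_bases <- function(gr_list, chrom, strand_sym, universe = 10000L) {
  v <- logical(universe)
  for (g in gr_list) {
    g <- g[as.character(seqnames(g)) == chrom &
             as.character(strand(g)) == strand_sym]
    for (i in seq_along(g)) v[start(g)[i]:end(g)[i]] <- TRUE
  }
  sum(v)
}

# unique bases of a set of 1-based inclusive intervals
oracle_unique_bases <- function(start1, end1, universe = 10000L) {
  v <- logical(universe)
  for (i in seq_along(start1)) v[start1[i]:end1[i]] <- TRUE
  sum(v)
}

# random non-overlapping coverage track on one chromosome
random_track <- function(id, chrom = "chrT", n = 15L, max_end = 2000L) {
  bounds <- sort(sample(seq_len(max_end), 2L * n))
  starts <- bounds[seq(1L, 2L * n, by = 2L)]
  ends <- bounds[seq(2L, 2L * n, by = 2L)]
  coverage_track(id, GRanges(chrom, IRanges::IRanges(starts, ends),
                             score = sample(0:8, n, replace = TRUE)))
}

random_sites <- function(rbp, chrom = "chrT", n = 8L, max_end = 2000L) {
  starts <- sample(seq_len(max_end - 60L), n)
  binding_site_set(rbp, "lineA",
                   GRanges(chrom,
                           IRanges::IRanges(starts, starts + sample(10:50, n, replace = TRUE)),
                           strand = sample(c("+", "-"), n, replace = TRUE)))
}

# LocusCountMatrix from a plain counts matrix, loci laid out disjointly
make_lcm <- function(counts, rbp = "RBPX", chrom = "chrT", offset = 0L) {
  L <- nrow(counts)
  starts <- offset + seq_len(L) * 100L
  loci <- GRanges(chrom, IRanges::IRanges(starts, starts + 20L),
                  strand = "+")
  locus_count_matrix(loci, colnames(counts) %||%
                       sprintf("S%02d", seq_len(ncol(counts))),
                     counts, rbp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
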