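#!/usr/bin/env Rscript
# Stage 2: read the simulated bedGraphs and BED site sets back from disk
# and build the intersection products: the RBP-centric count matrices, a
# sample-centric atom x RBP matrix for one sample, and the biotype
# annotation summary. Writes TSV matrices under results/intersect/.

suppressPackageStartupMessages(library(exrbp))

sim_dir <- "results/sim"
out_dir <- "results/intersect"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate.R first")

bed <- sort(list.files(sim_dir, pattern = "^RBP[0-9]+\\.bed$",
                       full.names = TRUE))
sites <- lapply(bed, function(f)
  read_sites(f, sub("\\.bed$", "", basename(f)), "merged"))
names(sites) <- vapply(sites, `[[`, "", "rbp")

bg <- sort(list.files(sim_dir, pattern = "\\.bedgraph$", full.names = TRUE))
tracks <- lapply(bg, function(f) read_coverage(f))
cat(sprintf("read %d site sets and %d coverage tracks\n",
            length(sites), length(tracks)))

# RBP-centric matrices (read-count proxy: per-base maximum)
for (r in names(sites)) {
  m <- build_rbp_matrix(tracks, sites[[r]])
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(m$loci)),
                   start = GenomicRanges::start(m$loci) - 1L,
                   end = GenomicRanges::end(m$loci),
                   strand = as.character(GenomicRanges::strand(m$loci)),
                   m$counts, check.names = FALSE)
  write.table(df, file.path(out_dir, paste0(r, ".counts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# sample-centric view for the first sample: atoms x RBPs
sm <- build_sample_matrix(tracks[[1]], unname(sites))
df <- data.frame(chrom = as.character(GenomicRanges::seqnames(sm$atoms)),
                 start = GenomicRanges::start(sm$atoms) - 1L,
                 end = GenomicRanges::end(sm$atoms),
                 members = vapply(sm$members, paste, "", collapse = ";"),
                 sm$counts, check.names = FALSE)
write.table(df, file.path(out_dir, "sample1_atom_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("sample-centric matrix: %d atoms x %d RBPs (%d multi-RBP atoms)\n",
            nrow(df), length(sm$rbp_columns),
            sum(lengths(sm$members) > 1)))

# biotype annotation of each RBP's loci
ann <- read_annotation(file.path(sim_dir, "annotation.bed"))
bt <- do.call(rbind, lapply(names(sites), function(r) {
  counts <- annotate_loci(sites[[r]], ann)$biotype_counts
  data.frame(rbp = r, biotype = names(counts), n_loci = unname(counts))
}))
write.table(bt, file.path(out_dir, "biotype_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("biotype locus counts written; top biotypes:\n")
print(head(sort(tapply(bt$n_loci, bt$biotype, sum), decreasing = TRUE)))
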