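#!/usr/bin/env Rscript
# Stage 5: the 4-sample EV permutation analysis. Reads the simulated EV
# count matrices, filters eligible RBPs (>= 15 loci with reads in >= 2 of
# the samples), tests cross-sample consistency by the pooled-CV
# permutation test, and estimates the cohort FDR from size-matched
# randomized locus sets. Tables go to results/ev/.

suppressPackageStartupMessages(library(exrbp))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

sim_dir <- "results/sim"
out_dir <- "results/ev"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate.R first")

files <- sort(list.files(sim_dir, pattern = "\\.ev_counts\\.tsv$",
                         full.names = TRUE))
matrices <- lapply(files, function(f) {
  d <- read.table(f, header = TRUE, sep = "\t")
  as.matrix(d[, -1])
})
names(matrices) <- sub("\\.ev_counts\\.tsv$", "", basename(files))

res <- ev_cohort_test(matrices, n_perm = 1000, seed = seed)
write.table(rbind(res$true, res$random),
            file.path(out_dir, "cv_results.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

fdr <- cohort_fdr(res$true, res$random)
summary <- data.frame(n_tested = nrow(res$true),
                      n_sig_true = fdr$n_sig_true,
                      n_sig_random = fdr$n_sig_random,
                      fdr_percent = fdr$fdr_percent, ks_p = fdr$ks_p)
write.table(summary, file.path(out_dir, "cohort_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- readLines(file.path(sim_dir, "ground_truth.tsv"))
consistent <- strsplit(sub("ev_consistent=", "",
                           grep("^ev_consistent=", truth, value = TRUE)),
                       ",")[[1]]
called <- res$true$rbp[res$true$significant]
cat(sprintf("%d / %d RBPs significant (planted sensitivity %.2f, %d FP)\n",
            length(called), nrow(res$true),
            mean(consistent %in% called),
            sum(!(called %in% consistent))))
cat(sprintf("randomized sets: %d significant; estimated FDR %.1f%%; KS p = %.3g\n",
            fdr$n_sig_random, fdr$fdr_percent, fdr$ks_p))
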