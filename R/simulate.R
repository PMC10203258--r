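## Synthetic cohorts with planted ground truth.
##
## The generator emulates the statistical structure the footprint analysis
## assumes: sample-to-sample covariation of loci sharing a carrier
## (multiplicative latent carrier-abundance factors), independent
## background loci of matching marginal scale, partially overlapping
## binding-site sets across RBPs, strandedness, deconvolved cargo-type
## profiles, and small 4-sample EV-like sets. Counts follow a log-normal
## multiplicative model: for a planted exRBP c, sample s and locus l,
## count = round(baseline_l * f(c, s) * eps) with f ~ logN(0,
## latent_factor_sd^2) shared by all of c's loci and eps ~ logN(0,
## noise_sd^2) independent, giving expected pairwise log-scale locus
## correlation latent_factor_sd^2 / (latent_factor_sd^2 + noise_sd^2).
## Everything is deterministic given the config seed; a toy two-chromosome
## mini-genome keeps per-base oracles tractable.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under:
#' cohorts of 100 samples, 20 RBPs with 30 binding-site loci each, 5
#' planted exRBPs with latent-factor covariation at log-scale correlation
#' 0.8^2 / (0.8^2 + 0.5^2) ~= 0.72, a 10% verbatim locus overlap between
#' neighbouring RBP site sets, six cargo types, and 4-sample EV sets in
#' which 10 of 20 RBPs are planted consistent.
#'
#' @param seed Integer seed (mandatory; every draw derives from it).
#' @param n_samples Samples per cohort.
#' @param n_rbps Number of RBPs.
#' @param loci_per_rbp Binding-site loci per RBP.
#' @param n_planted_exrbps Planted exRBPs (carrier covariation).
#' @param latent_factor_sd Log-scale sd of the per-sample carrier factor.
#' @param noise_sd Log-scale sd of per-locus multiplicative noise.
#' @param baseline_count_mean Median baseline count per locus.
#' @param baseline_log_sd Log-scale sd of per-locus baselines.
#' @param overlap_fraction Fraction of each RBP's loci shared verbatim
#'   with the next RBP's set (exercises unique-locus removal).
#' @param biotype_labels Biotype vocabulary for the annotation.
#' @param n_cts Number of cargo types (6 gives the CT1..CT4 labels).
#' @param ct_contrast Fold excess of assigned-CT coverage.
#' @param ct_noise_sd Log-scale noise on CT profiles.
#' @param n_ev_samples EV samples (4, as in an RBC EV experiment).
#' @param n_ev_consistent Planted consistent RBPs in the EV set (default:
#'   half of `n_rbps`).
#' @param ev_base_mean Median EV locus count.
#' @param ev_profile_sd Log-scale spread of EV locus baselines.
#' @param ev_lib_sd Log-scale spread of EV sample library scales.
#' @param ev_noise_sd Log-scale EV measurement noise.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_samples = 100L,
                       n_rbps = 20L,
                       loci_per_rbp = 30L,
                       n_planted_exrbps = 5L,
                       latent_factor_sd = 0.8,
                       noise_sd = 0.5,
                       baseline_count_mean = 20,
                       baseline_log_sd = 0.3,
                       overlap_fraction = 0.1,
                       biotype_labels = c("miRNA", "tRNA", "piRNA",
                                          "snoRNA", "lincRNA"),
                       n_cts = 6L,
                       ct_contrast = 4,
                       ct_noise_sd = 0.1,
                       n_ev_samples = 4L,
                       n_ev_consistent = NULL,
                       ev_base_mean = 30,
                       ev_profile_sd = 0.3,
                       ev_lib_sd = 0.8,
                       ev_noise_sd = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_rbps = as.integer(n_rbps),
              loci_per_rbp = as.integer(loci_per_rbp),
              n_planted_exrbps = as.integer(n_planted_exrbps),
              latent_factor_sd = latent_factor_sd, noise_sd = noise_sd,
              baseline_count_mean = baseline_count_mean,
              baseline_log_sd = baseline_log_sd,
              overlap_fraction = overlap_fraction,
              biotype_labels = biotype_labels, n_cts = as.integer(n_cts),
              ct_contrast = ct_contrast, ct_noise_sd = ct_noise_sd,
              n_ev_samples = as.integer(n_ev_samples),
              n_ev_consistent = as.integer(n_ev_consistent %||%
                                             max(1, round(n_rbps / 2))),
              ev_base_mean = ev_base_mean, ev_profile_sd = ev_profile_sd,
              ev_lib_sd = ev_lib_sd, ev_noise_sd = ev_noise_sd)
  stopifnot(cfg$n_samples >= 1, cfg$n_rbps >= 1, cfg$loci_per_rbp >= 1,
            cfg$n_planted_exrbps >= 0,
            cfg$n_planted_exrbps <= cfg$n_rbps,
            cfg$latent_factor_sd >= 0, cfg$noise_sd >= 0,
            cfg$overlap_fraction >= 0, cfg$overlap_fraction < 1,
            cfg$n_cts >= 2, cfg$n_ev_samples >= 2,
            cfg$n_ev_consistent <= cfg$n_rbps)
  structure(cfg, class = "sim_config")
}

ct_labels <- function(n_cts) {
  if (n_cts == 6L) c("CT1", "CT2", "CT3A", "CT3B", "CT3C", "CT4")
  else paste0("CT", seq_len(n_cts))
}

rbp_names <- function(n) sprintf("RBP%02d", seq_len(n))

#' Simulate binding-site sets and a biotype annotation
#'
#' Lays out non-overlapping loci on a two-chromosome mini-genome and
#' assigns each locus a primary RBP; a controlled fraction of each RBP's
#' loci is shared verbatim with the next RBP's set (cyclic), so
#' `overlap_fraction = 0` makes every atom single-membered. Annotation
#' records (with occasional double biotypes and a small unannotated
#' remainder) overlap designated loci.
#'
#' @param config A [sim_config()].
#' @return List with `sites` (named list of `BindingSiteSet`, site
#'   `locus_id`s in `mcols`), `annotation` (`AnnotationSet`), `loci`
#'   (`GRanges` of distinct loci with `locus_id` and `primary_rbp`) and
#'   `rbps`.
#' @export
simulate_sites <- function(config) {
  stopifnot(is(config, "sim_config"))
  k_shared <- round(config$overlap_fraction * config$loci_per_rbp)
  n_own <- config$loci_per_rbp - k_shared
  if (config$n_rbps > 1L && k_shared > n_own)
    stop("overlap_fraction infeasible: shared loci exceed own loci")
  if (config$n_rbps == 1L && k_shared > 0L)
    stop("overlap_fraction must be 0 with a single RBP")
  rbps <- rbp_names(config$n_rbps)
  D <- config$n_rbps * n_own
  with_seed(config$seed + 1L, {
    widths <- sample(30:60, D, replace = TRUE)
    gaps <- sample(60:160, D, replace = TRUE)
    half <- ceiling(D / 2)
    chrom <- rep(c("chrA", "chrB"), times = c(half, D - half))
    pos <- unlist(lapply(split(seq_len(D), chrom), function(i) {
      cumsum(gaps[i]) + c(0, cumsum(widths[i]))[seq_along(i)]
    }), use.names = FALSE)
    ord <- order(chrom)  # positions were computed per chromosome
    loci <- GRanges(chrom[ord], IRanges(start = pos + 1L,
                                        width = widths[ord]),
                    strand = sample(c("+", "-"), D, replace = TRUE))
    # scatter primary RBPs across the layout
    loci$locus_id <- sprintf("L%04d", seq_len(D))
    loci$primary_rbp <- sample(rep(rbps, each = n_own))
    sites <- list()
    for (i in seq_along(rbps)) {
      own <- loci[loci$primary_rbp == rbps[i]]
      borrowed <- if (k_shared > 0L) {
        nxt <- rbps[if (i == config$n_rbps) 1L else i + 1L]
        donor <- loci[loci$primary_rbp == nxt]
        donor[sort(sample(length(donor), k_shared))]
      } else loci[integer(0)]
      g <- c(own, borrowed)
      g$primary_rbp <- NULL
      sites[[rbps[i]]] <- binding_site_set(rbps[i], "merged",
                                           sort(g, ignore.strand = TRUE))
    }
    # annotation: per-RBP preferred biotype, ~90% of loci annotated
    pref <- stats::setNames(
      rep(config$biotype_labels, length.out = config$n_rbps), rbps)
    annotated <- runif(D) < 0.9
    bt <- ifelse(runif(D) < 0.6, pref[loci$primary_rbp],
                 sample(config$biotype_labels, D, replace = TRUE))
    agr <- loci[annotated]
    agr <- resize(agr, width(agr) + 20L, fix = "center")
    mcols(agr) <- NULL
    agr$gene_id <- sprintf("G%04d", seq_along(agr))
    agr$biotype <- unname(bt[annotated])
    agr$gene_name <- sprintf("GENE%04d", seq_along(agr))
    # ~5% carry a second record with a different biotype
    dbl <- which(runif(length(agr)) < 0.05)
    if (length(dbl)) {
      extra <- agr[dbl]
      extra$biotype <- vapply(extra$biotype, function(b)
        sample(setdiff(config$biotype_labels, b), 1L), "")
      agr <- c(agr, extra)
    }
    list(sites = sites, annotation = annotation_set(agr),
         loci = loci, rbps = rbps)
  })
}

#' Simulate an exRNA cohort with planted carrier covariation
#'
#' Per sample s and planted exRBP c, a latent carrier-abundance factor
#' `f(c, s) ~ logN(0, latent_factor_sd^2)` multiplies the baselines of all
#' of c's loci; independent multiplicative noise `logN(0, noise_sd^2)` is
#' applied per (locus, sample). Loci of non-planted RBPs draw independent
#' counts of matching marginal scale (`logN(0, latent_factor_sd^2 +
#' noise_sd^2)`), so coverage-based null matching is non-degenerate.
#' Shared loci inherit their primary (donor) RBP's counts, keeping tracks
#' single-valued per genomic position.
#'
#' @param config A [sim_config()].
#' @param sites Result of [simulate_sites()].
#' @param tracks Also emit per-sample `CoverageTrack`s (site intervals
#'   valued with their counts, zeros omitted).
#' @return List with `matrices` (named list of `LocusCountMatrix`, one
#'   per RBP), `locus_counts` (distinct loci x samples), `samples`,
#'   `tracks` (optional) and `truth` (planted exRBPs, per-locus carrier,
#'   latent factor matrix).
#' @export
simulate_cohort <- function(config, sites, tracks = FALSE) {
  stopifnot(is(config, "sim_config"))
  loci <- sites$loci
  D <- length(loci)
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  with_seed(config$seed + 2L, {
    planted <- sort(sample(sites$rbps, config$n_planted_exrbps))
    b <- rlnorm(D, log(config$baseline_count_mean), config$baseline_log_sd)
    factors <- base::matrix(
      rlnorm(length(planted) * config$n_samples, 0, config$latent_factor_sd),
      nrow = length(planted), ncol = config$n_samples,
      dimnames = list(planted, samples))
    counts <- base::matrix(0, D, config$n_samples,
                           dimnames = list(loci$locus_id, samples))
    sd_marginal <- sqrt(config$latent_factor_sd^2 + config$noise_sd^2)
    for (i in seq_len(D)) {
      pr <- loci$primary_rbp[i]
      counts[i, ] <- if (pr %in% planted) {
        round(b[i] * factors[pr, ] *
                rlnorm(config$n_samples, 0, config$noise_sd))
      } else {
        round(b[i] * rlnorm(config$n_samples, 0, sd_marginal))
      }
    }
    matrices <- lapply(sites$sites, function(s) {
      locus_count_matrix(s$gr, samples,
                         counts[s$gr$locus_id, , drop = FALSE], s$rbp)
    })
    out <- list(matrices = matrices, locus_counts = counts,
                samples = samples,
                truth = list(planted_exrbps = planted,
                             carrier = stats::setNames(loci$primary_rbp,
                                                       loci$locus_id),
                             factors = factors))
    if (tracks) {
      out$tracks <- lapply(samples, function(s) {
        nz <- counts[, s] > 0
        g <- granges(loci[nz])
        strand(g) <- "*"
        g$score <- unname(counts[nz, s])
        coverage_track(s, g)
      })
      names(out$tracks) <- samples
    }
    out
  })
}

#' Simulate deconvolved cargo-type profiles
#'
#' Assigns each RBP 1-3 cargo types and concentrates per-base coverage in
#' the assigned CTs with a configurable fold contrast over the baseline
#' leakage in the remaining CTs.
#'
#' @param config A [sim_config()].
#' @param sites Result of [simulate_sites()].
#' @return List with `profiles` (named list of loci x CT coverage
#'   matrices) and `assignments` (named list of planted CT labels per
#'   RBP).
#' @export
simulate_ct_profiles <- function(config, sites) {
  stopifnot(is(config, "sim_config"))
  labels <- ct_labels(config$n_cts)
  with_seed(config$seed + 3L, {
    assignments <- lapply(sites$rbps, function(r)
      sort(sample(labels, sample(1:3, 1L))))
    names(assignments) <- sites$rbps
    profiles <- lapply(sites$rbps, function(r) {
      L <- length(sites$sites[[r]]$gr)
      base <- rlnorm(L, log(5), 0.3)
      mult <- 1 + config$ct_contrast * (labels %in% assignments[[r]])
      m <- outer(base, mult) *
        base::matrix(rlnorm(L * config$n_cts, 0, config$ct_noise_sd),
                     L, config$n_cts)
      colnames(m) <- labels
      m
    })
    names(profiles) <- sites$rbps
    list(profiles = profiles, assignments = assignments)
  })
}

#' Simulate 4-sample EV count matrices
#'
#' Consistent RBPs have locus profiles proportional across samples
#' (locus baseline x sample library scale x small noise); inconsistent
#' RBPs draw every cell independently with the same marginal log-normal
#' scale, so marginal count distributions match.
#'
#' @param config A [sim_config()].
#' @param sites Result of [simulate_sites()].
#' @return List with `matrices` (named list, loci x samples) and
#'   `consistent` (planted consistent RBP names).
#' @export
simulate_ev_samples <- function(config, sites) {
  stopifnot(is(config, "sim_config"))
  with_seed(config$seed + 4L, {
    consistent <- sort(sample(sites$rbps, config$n_ev_consistent))
    sd_marginal <- sqrt(config$ev_profile_sd^2 + config$ev_lib_sd^2 +
                          config$ev_noise_sd^2)
    S <- config$n_ev_samples
    matrices <- lapply(sites$rbps, function(r) {
      L <- length(sites$sites[[r]]$gr)
      m <- if (r %in% consistent) {
        p <- rlnorm(L, log(config$ev_base_mean), config$ev_profile_sd)
        a <- rlnorm(S, 0, config$ev_lib_sd)
        round(p %o% a * base::matrix(rlnorm(L * S, 0, config$ev_noise_sd),
                                     L, S))
      } else {
        base::matrix(round(rlnorm(L * S, log(config$ev_base_mean),
                                  sd_marginal)), L, S)
      }
      dimnames(m) <- list(sites$sites[[r]]$gr$locus_id,
                          sprintf("EV%d", seq_len(S)))
      m
    })
    names(matrices) <- sites$rbps
    list(matrices = matrices, consistent = consistent)
  })
}

#' Write a full simulation to disk
#'
#' Emits, under one directory: a bedGraph per sample, a BED6 per RBP, the
#' annotation BED, per-RBP CT profile TSVs, EV matrix TSVs, and a
#' ground-truth manifest (TSV key=value pairs echoing the config plus the
#' planted truths) with a human-readable summary. All outputs are plain
#' text and round-trip through the package readers.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return Invisibly, the list of generated objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- simulate_sites(config)
  cohort <- simulate_cohort(config, sites, tracks = TRUE)
  cts <- simulate_ct_profiles(config, sites)
  ev <- simulate_ev_samples(config, sites)

  for (s in names(cohort$tracks))
    write_coverage(cohort$tracks[[s]], file.path(dir, paste0(s, ".bedgraph")))
  for (r in names(sites$sites))
    write_sites(sites$sites[[r]], file.path(dir, paste0(r, ".bed")),
                names = sites$sites[[r]]$gr$locus_id)
  agr <- sites$annotation$gr
  ann_df <- data.frame(chrom = as.character(seqnames(agr)),
                       start = start(agr) - 1L, end = end(agr),
                       gene_id = agr$gene_id, biotype = agr$biotype,
                       gene_name = agr$gene_name,
                       strand = as.character(strand(agr)))
  ann_df$strand[ann_df$strand == "*"] <- "."
  write.table(ann_df, file.path(dir, "annotation.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (r in names(cts$profiles))
    write.table(data.frame(locus_id = sites$sites[[r]]$gr$locus_id,
                           cts$profiles[[r]], check.names = FALSE),
                file.path(dir, paste0(r, ".ct_profile.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  for (r in names(ev$matrices))
    write.table(data.frame(locus_id = rownames(ev$matrices[[r]]),
                           ev$matrices[[r]], check.names = FALSE),
                file.path(dir, paste0(r, ".ev_counts.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)

  manifest <- c(
    vapply(names(unclass(config)), function(k)
      paste(k, paste(config[[k]], collapse = ","), sep = "="), ""),
    paste0("planted_exrbps=",
           paste(cohort$truth$planted_exrbps, collapse = ",")),
    paste0("ev_consistent=", paste(ev$consistent, collapse = ",")),
    vapply(names(cts$assignments), function(r)
      paste0("ct_assignment.", r, "=",
             paste(cts$assignments[[r]], collapse = ",")), ""))
  writeLines(manifest, file.path(dir, "ground_truth.tsv"))
  writeLines(c(
    sprintf("Synthetic exRNA cohort (seed %d)", config$seed),
    sprintf("%d samples, %d RBPs x %d loci, %d planted exRBPs",
            config$n_samples, config$n_rbps, config$loci_per_rbp,
            config$n_planted_exrbps),
    sprintf("planted exRBPs: %s",
            paste(cohort$truth$planted_exrbps, collapse = ", ")),
    sprintf("EV-consistent RBPs: %s", paste(ev$consistent, collapse = ", "))),
    file.path(dir, "ground_truth_summary.txt"))
  invisible(list(sites = sites, cohort = cohort, cts = cts, ev = ev))
}
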