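---
title: "Correlation footprinting of extracellular RNA-binding proteins: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation footprinting of extracellular RNA-binding proteins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exrbp)
```

# The model

Extracellular RNA travels in carriers — vesicles, lipoprotein particles,
ribonucleoprotein complexes — whose relative abundance varies strongly
between biofluid samples. If an RNA-binding protein (RBP) carries exRNA,
that carrier-abundance variation acts as a shared multiplicative factor
on the read coverage of *all* loci bound by that RBP. The footprint
statistic turns this into a testable contrast: loci of an exRBP should be
more strongly pairwise-correlated across samples than coverage-matched
loci belonging to other RBPs.

The package's generative picture (and the synthetic generator's model) is
log-normal and multiplicative: for planted exRBP $c$, locus $\ell$, and
sample $s$,

$$x_{\ell s} = \mathrm{round}\!\left(b_\ell \, f_{cs} \,
\varepsilon_{\ell s}\right), \qquad
f_{cs} \sim \log\mathcal{N}(0, \sigma_f^2), \quad
\varepsilon_{\ell s} \sim \log\mathcal{N}(0, \sigma_e^2),$$

with locus baselines $b_\ell$. On the log scale the expected pairwise
locus correlation is $\sigma_f^2 / (\sigma_f^2 + \sigma_e^2)$, which
gives the generator an analytic test hook (checked by Monte-Carlo in the
test suite). Background loci draw independent counts with matched
marginal scale $\log\mathcal{N}(0, \sigma_f^2 + \sigma_e^2)$, so
coverage-based null matching cannot separate planted from background loci
by their marginals.

# From coverage to counts

Coverage arrives as bedGraph (0-based half-open); binding sites as
BED6/narrowPeak. All internal coordinates are 0-based half-open, the
native convention of those formats; prose coordinates like `chr1:1-10`
(1-based inclusive) convert as $[a,b] \rightarrow [a-1, b)$.

The read-count proxy for a site is an aggregate of per-base depth inside
it, **maximum** by default. Rationale: exRNA fragments are shorter than
sequencing reads, so identical stacked fragments produce a depth equal to
the read count at the fragment; the per-base maximum recovers it without
double-counting bases. The aggregation operator is configurable
(`max | sum | mean`) because the exact operator used by any particular
upstream pipeline is rarely documented; every operator is verified
against a per-base brute-force oracle in the tests.

Two matrix layouts exist: RBP-centric (one RBP's sites × all samples,
`build_rbp_matrix()`) and sample-centric (atomic regions × RBPs for one
sample, `build_sample_matrix()`). Atomic regions are maximal intervals
over which the covering-RBP set is constant; two sites `chr1:1-10` (RBP
A) and `chr1:5-15` (RBP B) partition into `chr1:1-5`, `chr1:6-10`,
`chr1:11-15` with memberships {A}, {A,B}, {B}. Strand is ignored when
partitioning (sample-centric intersections are unstranded); the
off-strand fraction of coverage is quantified separately by
`off_strand_percent()` from strand-split tracks. Cross-cell-line merging
of one RBP's two site sets *is* strand-aware, and coalesces book-ended
intervals (conventional merge semantics; whether book-ended eCLIP peaks
should coalesce is not documented anywhere we know of, and the
alternative only changes locus counts, not any downstream statistic,
because book-ended peaks are rare in practice).

# The two-stage footprint test

For one RBP with usable loci $1..L$ (nonzero variance across samples;
all-zero rows and loci shared between RBPs removed first):

1. **Coverage matching.** Each locus's coverage scalar is its total
   count summed over samples. A null locus is drawn uniformly among the
   other RBPs' loci with equal coverage; failing that, coverage $+1$
   (when any pool locus exceeds the target), else $-1$; the chain
   extends to $\pm 2, \pm 3, \dots$ with an `exhausted` flag once the
   matched distance exceeds 1. Ties break uniformly under the run seed.
2. **Per-locus KS.** For locus $i$ with matched null $n_i$: distribution
   1 is the Pearson correlations of $i$ against the RBP's other loci;
   distribution 2 is the correlations of $n_i$ against *all* the RBP's
   loci. $p_i$ is the two-sided two-sample KS p-value comparing them.
   Correlations are computed on raw counts — no log transform — because
   the footprint contrast is against equally-raw null correlations and
   the monotone transform mostly cancels in the comparison.
3. **Mirrored null.** $q_i$ repeats step 2 with roles swapped: $n_i$
   against the other matched nulls, versus locus $i$ against all matched
   nulls. Under the global null the construction is exchangeable with
   step 2 by design.
4. **Aggregation.** The RBP's raw p-value is the one-sided two-sample KS
   test of whether $\{p_i\}$ is stochastically smaller than $\{q_i\}$,
   plus an explicit direction check
   $\mathrm{median}(p_i) < \mathrm{median}(q_i)$. A one-sided test with
   a direction gate was chosen over a two-sided test with post-hoc
   filtering so that "more correlated than random" is the only rejection
   direction.

The screen repeats this under six locus filters — at least
{30, 20, 10} samples with count ≥ 5, and the same with count ≥ 2 — and
Bonferroni-multiplies each raw p by the number of RBPs tested in that
(cohort, filter) run. The Bonferroni family is per filter run; spanning
filters as well would double-penalize the (deliberately redundant) grid,
and spanning cohorts would couple unrelated analyses. An RBP is called
when significant, in direction, in at least one filter set; the smallest
adjusted p across filters is reported. Biotype-restricted screening
(`biotype_footprint()`) subsets each RBP's loci to one biotype and
re-runs the identical procedure; the matching pool remains the other
RBPs' full locus sets so that matching stays non-degenerate for rare
biotypes.

## Calibration, and a known conservatism

The test suite calibrates the procedure on all-noise cohorts (60
samples, 20 RBPs × 30 loci, 200 replicates). Two properties of the
aggregation make the per-RBP raw p conservative at small locus counts:
the one-sided two-sample KS statistic on 30-vs-30 p-value samples lives
on a lattice (multiples of 1/30), so the achievable size at nominal 0.05
is $\binom{60}{20}/\binom{60}{30} \approx 0.035$; and the per-locus
$p_i$ (and $q_i$) share correlation pools, and that positive dependence
is not modelled by the KS null of independent samples. The measured null
rejection rate at raw $\alpha = 0.05$ in the suite is ≈ 0.02–0.03,
below the exact binomial band around 0.05 — the test under-rejects, it
never over-rejects. Power at the default study conditions is unaffected
in practice: the planted-truth suite recovers 5/5 planted exRBPs with 0
false positives among 15 null RBPs.

Open choices resolved here: the correlation *coefficients* (not
correlation-test p-values) feed the per-locus KS comparison — the
comparison is symmetric either way, and coefficients avoid an arbitrary
choice of correlation-test; per-locus KS tests use asymptotic p-values
(`exact = FALSE`) on both the true and mirrored side, so the convention
cancels in the aggregate.

# Cargo-type enrichment

Deconvolved carrier profiles give each locus an average per-base
coverage in each of six cargo types (CT1 low-density vesicles, CT2
lipoprotein particles, CT3A/B/C ribonucleoprotein-associated, CT4
high-density vesicles). The deconvolution itself is consumed as input —
it is a separately published method — and the synthetic generator emits
ground-truth CT profiles directly. Per RBP,

$$\mathrm{score}(CT) = \frac{\text{mean over loci of per-base coverage
in } CT}{\text{unweighted mean over CTs of the per-CT means}}.$$

The grand mean uses equal CT weights, which is exactly what makes each
row average to 1 (tolerance $10^{-9}$ in the tests); rows with zero
grand-mean coverage are dropped with a warning rather than propagating
NaN. Cells with score ≥ 1.4 are enriched — the threshold sits just above
the 75th percentile of observed scores in the motivating analysis (1.34;
`enrichment_percentile()` recomputes the percentile on any table), and
the non-strict ≥ is used since nothing distinguishes the two readings at
a round cutoff. Raising the threshold never adds a CT to any set
(monotonicity, tested).

Fraction concordance: density-gradient fraction classes pair with CTs as
fractions 1–3 ↔ CT4, 4–7 ↔ CT1, 9–12 ↔ CT2, unfractionated ↔ CT3
(A/B/C). The source material also contains a second, contradictory
pairing (CT1 ↔ 9–12, CT2 ↔ 4–7); both are implemented
(`ct_fraction_mapping("results" | "methods")`) and neither is asserted
as intent — the default is the mapping stated with the fraction data
themselves. An RBP is consistent when at least one enriched CT maps to
an enriched fraction class.

Biotype bound-fractions: per study and CT, a binding site is expressed
when one sample reaches 5 reads and its estimated CT count reaches 2;
the fraction for a biotype is the unique bases of genes overlapping a
passing site divided by the unique bases of all the biotype's genes
(non-strand-specific overlap, unique-base counting via interval union —
verified against a per-base oracle). Kruskal–Wallis across CTs per
biotype; when the omnibus p < 0.05, pairwise Wilcoxon rank-sum tests
with Holm adjustment. A biotype with identical fractions everywhere
reports an omnibus p of 1 (no association), not a missing value.

# The EV permutation test

Four-sample EV cohorts cannot support correlation estimates, so
consistency of an RBP's locus profile across samples is scored by the
pooled coefficient of variation: all absolute pairwise between-sample
differences $|x_{\ell s} - x_{\ell t}|$ (6 pairs × L loci) enter one
pool, and $CV = 100\,\sigma/\mu$ over the pool. Absolute values are
used because signed differences pool to mean ≈ 0 and make $\sigma/\mu$
unstable. An all-zero difference pool (perfect consistency) is defined
as CV 0. Loci need a nonzero count in ≥ 2 of the 4 samples, RBPs ≥ 15
such loci; the "below 0.05" significance rule is read as a permutation
*p-value* below 0.05 — a CV is on a percent scale, where 0.05 would be
absurdly small.

**Null model.** The permutation null shuffles *all cells* of the
loci × samples matrix. A tempting alternative — permuting each locus's
row independently — is provably degenerate for this statistic: the
multiset of pairwise absolute differences within a row is invariant
under any permutation of that row, so every "permuted" CV would equal
the observed one and p ≡ 1. The full shuffle destroys both locus
identity and sample assignment while preserving the count pool, and
under it planted-consistent matrices are detected (lower tail,
$p = (1 + \#\{CV_{null} \le CV_{obs}\})/(n_{perm}+1)$, floor
$1/(n_{perm}+1)$, 1000 permutations by default) while independent-cell
matrices are exchangeable with their shuffles, giving uniform p-values
up to the permutation lattice (calibrated over 200 null replicates in
the suite). Randomized control sets — per RBP, an equal-sized locus set
drawn from the other RBPs' eligible loci — feed the cohort FDR estimate
$100 \cdot n_{sig,random} / n_{sig,true}$ and a two-sample KS comparison
of the p-value distributions (the p-value reading of that comparison is
one of two possible; the variance-distribution reading would compare CV
values instead).

**Power regime.** The pooled CV only falls below its shuffled
counterpart when locus baselines are relatively homogeneous (log-sd
≈ 0.3) and sample-to-sample variation is dominated by a common library
scale (log-sd ≈ 0.8) with small residual noise — the generator's default
consistent-RBP regime, chosen by simulation before the tests were
written. With strongly heterogeneous locus baselines the statistic loses
its lower-tail power; this is a limitation of the CV formulation itself,
not of the permutation scheme.

# The synthetic generator

`sim_config()` defaults are the package's study conditions: 100 samples,
20 RBPs × 30 loci, 5 planted exRBPs, $\sigma_f = 0.8$, $\sigma_e = 0.5$
(log-scale pairwise correlation ≈ 0.72), baseline median count 20
(log-sd 0.3), 10% of each RBP's loci shared verbatim with the next RBP's
set (cyclic, to exercise unique-locus removal), six CTs with fold
contrast 4 and 1–3 assigned CTs per RBP, and 4-sample EV sets with half
the RBPs planted consistent. The mini-genome is two chromosomes of
≤ 0.5 Mb with loci of 30–60 bp, small enough for per-base oracles.
Counts are integerized by rounding, and zeros are allowed — they
exercise the all-zero-row and zero-variance code paths deliberately.
Everything derives deterministically from the config seed (the test
suite checks byte-identical re-emission).

What the generator does *not* emulate: read-level artifacts (alignment,
duplicates, soft-clipping), sequence content, biofluid-specific biotype
composition, batch effects between studies, and the long-range
correlation structure of real transcriptomes. A passing planted-truth
suite therefore shows that the statistics detect the modelled
carrier-covariation signal at realistic effect sizes — not that real
biofluid data meet the model.

# Problem sizes and numerical conventions

The test suite runs cohorts of 30–100 samples (2000 for the Monte-Carlo
closed-form check), 200-replicate calibrations for both permutation and
footprint nulls, and 1000-permutation EV tests; the whole suite
completes in a few minutes on one core. Other conventions: p-values are
capped at 1 after Bonferroni; zero-variance loci are excluded from both
true and null correlation pools; zero-length/negative intervals are
rejected at parse time; chromosome names are taken verbatim (a
track/site naming mismatch yields zero counts plus a warning, not an
error); gzip and plain text are read transparently; all tabular outputs
are sorted by (chrom, start).
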