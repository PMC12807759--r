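---
title: "Models and methods in m6akit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in m6akit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6akit)
```

# The problem

N6-methyladenosine (m6A) is profiled by assays built on four distinct
biochemical principles — antibody enrichment (MeRIP-seq, m6ACE-seq),
enzyme-assisted conversion or cleavage (eTAM-seq, MAZTER-seq, DART-seq),
chemical conversion (GLORI), and direct RNA sequencing. Each carries its own
artifacts, and catalogues built by intersecting published peak lists inherit
every upstream processing inconsistency. m6akit implements the alternative:
quantify every assay against one fixed, base-resolution reference set of
adenosines, call sites with one uniform statistical test, subtract what
modification-free controls "detect", and only believe sites whose
quantitative signal reproduces across technically *orthogonal* assays.

# Reference sites

The universal row space is the set of exonic DRACH adenosines
(D=A/G/T, R=A/G, A, C, H=A/C/T) of the canonical transcripts, scanned
strand-aware on the exon's sense sequence; minus-strand exons are scanned on
the reverse complement and reported at the genomic coordinate of the central
A. The 5-mer window must fit inside the exon, so the first and last two
bases of an exon cannot be sites. When the annotation does not flag
canonical transcripts, the longest transcript per gene substitutes — the
true canonical tag is an annotation-database concept that a bare GTF may
lack. External site lists (e.g. non-DRACH or intronic sites from a published
atlas) merge in verbatim with provenance `"external"` and no motif check.

# Quantification

Two counting contracts produce the integer layers `m6a_count` and
`total_count`, which are complete by construction (zeros, never gaps):

* **IP/input overlap** (antibody assays): `m6a` is the number of IP
  *fragments* — properly paired mates unified by their template span —
  overlapping the single-base site; `total` adds the same count from the
  paired input library. No MAPQ or duplicate filtering happens here; that is
  an upstream decision.
* **Conversion pileup** (chemical/enzymatic assays): at each site the read
  base is extracted complement-aware; bases in the `m6a_bases` set (default
  `A`, the protected base) are methylated evidence, bases in `total_bases`
  (default `A`,`G`) form the denominator, and reads showing deletions or
  other bases at the site are excluded from both.

Gene expression uses `rpkm = count / ((length/1e3) * (library/1e6))`.

# Uniform site calling

For one sample (or one aggregated column) the background rate is the
sample-wide methylation proportion `p0 = sum(m6a) / sum(total)`. Each site
with coverage is tested one-sided against it, `p = P(X >= k)`,
`X ~ Binomial(n, p0)`, with the exact tail at every coverage (`pbinom`
evaluates the survival function directly, so no approximation is needed).
Benjamini-Hochberg correction runs per column over exactly the testable
(`n > 0`) sites: including untestable sites would dilute the correction with
p-values equal to 1. Whether the original pipeline pools columns is not
documented; per-column is the conservative reading and is what the package
does.

A caveat that matters for testing: the exact tail of a *discrete* statistic
is super-uniform under the null — `P(P <= x) <= x` with strict inequality
almost everywhere at moderate coverage. Calibration checks therefore test
for the absence of anti-conservatism (the empirical CDF must not rise above
the diagonal, a one-sided Kolmogorov–Smirnov statistic), not two-sided
uniformity, which any discrete test fails by construction.

## The beta-binomial mixture (BBmix)

As a complementary classifier, counts are modelled as a two-component
beta-binomial mixture in mean/concentration form (`a = mu*phi`,
`b = (1-mu)*phi`): a low-`mu` background and a high-`mu` foreground. The
fit is EM with responsibilities in the E-step; the M-step maximizes each
component's weighted log-likelihood numerically on the
`logit(mu), log(phi)` scale, *starting from the current parameters* — a
generalized EM step, so the observed-data log-likelihood never decreases
(the suite asserts this on the trace). Initialization takes the component
means from the 10th/90th percentiles of `k/n` with `phi = 10`; five
randomly perturbed restarts keyed to the seed guard against local optima,
and the best likelihood wins. Components are relabelled so the foreground
has the larger mean. The posterior foreground probability classifies at
0.5. If every `k` is zero the prior is pinned to the lower boundary: with
no foreground evidence anywhere, no site should classify as methylated.

# IVT calibration

In-vitro-transcribed RNA contains no m6A, so any site the binomial caller
flags in an IVT library (counts aggregated over the technique's IVT
samples, BH < 0.05) is a technique-specific false positive. Both count
layers are zeroed at those sites for *every* sample of the technique.
Because the background rate and all aggregations are computed from the
masked layers, masked sites drop out of everything downstream
self-consistently, and masking is idempotent. The mask is applied per
technique rather than per sample — the controls characterize the chemistry,
not an individual library.

# Orthogonal validation (IDR)

Two assay categories are orthogonal when they differ, except direct RNA
sequencing versus antibody assays: the base-calling models of direct
sequencing are trained on antibody-derived data, so agreement between the
two is not independent evidence.

Within each technique, counts are aggregated over baseline samples (or per
condition), converted to beta values `beta = m6A / (m6A + A)`, and tied
values are broken with multiplicative uniform jitter on
`(1 - f, 1 + f)`, `f = 1e-4`, seeded and recorded (ties at exactly zero get
additive jitter on `(0, f)` — a multiple of zero would stay tied). Only
sites with aggregated coverage of at least 20 in *both* techniques enter
the fit, for stable beta estimates.

The reproducibility model is the Gaussian copula mixture: ranks are mapped
to `u = rank/(n+1)` (keeping pseudo-values finite), pseudo-values
`z = G^{-1}(u)` use the current marginal mixture CDF
`G = p N(mu, sigma^2) + (1-p) N(0,1)`, and the pair `(z1, z2)` is modelled
as `p` times a bivariate normal with mean `(mu, mu)`, variance `sigma^2`
and correlation `rho` (the reproducible component) plus `1-p` times an
independent standard normal (noise). Fitting interleaves one EM step with
each pseudo-value refresh and stops when the pseudo-log-likelihood change
drops below `1e-6`, from the conventional start
`mu = 0.1, sigma = 1, rho = 0.2, p = 0.5`. Parameters are clamped
(`rho` in `[1e-4, 0.999]`, `sigma >= 1e-3`, `p` in `[1e-4, 1-1e-4]`).

Two numerical points deserve emphasis. First, running the EM to full
convergence *between* refreshes lets the free signal component collapse
onto the fixed noise component on structureless data (`p -> 1`, every site
"reproducible") — the mixture is unidentifiable there; one step per refresh
is both the reference behaviour and the stable choice, and diffuse data
that exhausts `max_iter = 2000` is flagged unconverged while still
producing sane thresholded output. Second, per-step EM monotonicity (at
fixed pseudo-values) is exposed as `em_gain` in the fit for direct testing.

The *local* idr of a site is its posterior noise probability; the *global*
IDR is the running mean of local idr along the ranking — the expected
irreproducible fraction among all sites called at or above that site. The
threshold "IDR < 0.05" is applied to the global quantity, the ENCODE
convention; the local value is reported alongside. A site is orthogonally
validated when all three criteria hold: global IDR < 0.05, and BH-adjusted
binomial p < 0.05 in each technique, computed on the same aggregated,
coverage-filtered site set.

**Differential methylation** reuses the machinery with
`delta beta = beta_treated - beta_control` per technique as the paired
scores, after requiring coverage >= 20 in all four aggregates. Exactly
constant differences (e.g. treated == control) are flagged degenerate
before jitter.

# The QTL stage

Methylation enters QTL mapping as M-levels,
`M = log[(IP/sum(IP)) / (Input/sum(Input))]` (natural log), missing where
`IP + Input = 0`; when coverage exists but one side is zero, 0.5 is added
to both sides of that cell — the formula is otherwise infinite and the
source is silent on the remedy. The normalization chain is fixed: rows with
more than 20% missing cells go first, then columns with more than 80%
(strict inequalities, evaluated in that order); per-sample MA regression
against the row-mean pseudo-reference removes IP-efficiency trends (OLS
residuals are exactly orthogonal to the regressor, which the tests
exploit); natural cubic splines of per-site GC content (default `df = 4`,
exposed — the source names the spline but not the df; GC window ±50 bp)
remove sequence-composition trends; rows are z-scored and columns
quantile-normalized with average-rank ties.

Latent batch structure is estimated by SVD on the covariate-residualized
matrix: the number of factors is the leading run of singular-value variance
proportions exceeding the 90th percentile of `B = 20` row-permutation
nulls. The factor count is always estimated from the data at hand, never
hard-coded from any particular corpus.

Cis windows are the union of the host gene's body span and the strand-aware
promoter `[TSS - 2000, TSS + 200]`. Association is OLS of the normalized
M-level on dosage with covariates; in practice phenotype and dosages are
residualized on the covariates once and the test reduces to a correlation
t-test. Per site, the best nominal p over cis variants is compared with the
same statistic under `n_perm` permutations of the residualized phenotype:
the direct empirical p is `(1 + #{perm <= obs}) / (1 + n_perm)` and a
`Beta(a, b)` fitted by maximum likelihood to the permutation minima gives
the smoothed empirical p and the per-site nominal thresholds at the 0.1
(low) and 0.05 (high) stringency tiers. Note the direct estimator is itself
an ECDF over `n_perm` draws, with pointwise Monte-Carlo noise of about
0.016 at mid-range p for 1000 permutations — agreement between the two
estimators is therefore asserted per-site only in the discovery-relevant
tail and on average elsewhere.

# The synthetic world

The generators state a fixed world; tests measure the pipeline against it:

* toy genomes (2 chromosomes × 50 kb by default, 20 genes of 1–5 exons on
  both strands) with every exonic DRACH recorded by an independent
  brute-force scan;
* methylomes with foreground probability `pi = 0.2`,
  `theta_fg ~ Beta(6, 4)`, `theta_bg ~ Beta(1, 50)`, depth negative
  binomial with mean 50 and dispersion 0.3 (dispersed rather than constant
  to stress the coverage filters), `k ~ Binomial(n, theta)`. A `bg_theta`
  option fixes the background at a constant — the exact global null of the
  binomial caller, which the heterogeneous Beta background is *not* (its
  upper tail is genuinely enriched relative to the pooled rate, and the
  caller correctly finds ~1% of it);
* SAM reads realizing given `(k, n)` cells for both counting contracts;
  conversion is applied only at the target base, which is sufficient for
  exact round-trip checks but does not model full-molecule chemistry; reads
  covering a neighbouring site pile up there too, exactly as in real data,
  so exact round trips use sites thinned to one read length apart;
* technique pairs sharing `theta ~ Beta(6, 4)` on a reproducible fraction
  of sites (logit-normal technique noise, sd 0.3) and independent
  `Beta(1, 50)` elsewhere;
* IVT controls with `k ~ Binomial(n, 0.01)` at expression-matched coverage;
* QTL cohorts with Hardy–Weinberg dosages (MAF uniform on 0.05–0.5), two
  real covariates, and planted per-site causal effects in noise-sd units.

A green suite therefore establishes internal statistical correctness —
exact tails, calibrated error rates, parameter recovery, exact round trips
— not concordance with any particular laboratory dataset: the generators
deliberately omit alignment artifacts, sequence-composition bias in reads,
overdispersion beyond the stated forms, and linkage structure in genotypes.

# Known limitations

* The published headline catalogue numbers require the full multi-sample
  raw corpus and are out of desk-scale reach by design; nothing here claims
  them.
* Only pairwise (two-technique) IDR is implemented; multi-way joint
  modelling is out of scope.
* Machine-learning IVT calibration for antibody data is not reimplemented
  (it depends on an externally trained model); the binomial IVT path is
  offered for every technique with controls.
* Direct-RNA per-site probabilities are ingested as precomputed counts, not
  recomputed from signal.
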