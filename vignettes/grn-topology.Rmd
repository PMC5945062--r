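---
title: "Scale-free topology of gene regulatory networks: models, inference and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-free topology of gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grntopo)
```

## The scientific problem

A gene regulatory network (GRN) is a directed graph in which an edge runs
from a transcription factor (TF) to a gene whose regulatory region it binds
— one protein–DNA interaction (PDI). Experimentally mapped GRNs are
incomplete samples of the complete, genome-wide regulatory repertoire: only
a fraction of the TFs encoded in a genome have been assayed. `grntopo`
implements the statistical machinery needed to (i) establish whether the
out-degree distribution of an observed GRN is scale-free, (ii) quantify the
inequality of TF–target binding that the scaling exponent encodes, and
(iii) extrapolate from the observed network to the complete one: a
prediction interval for the complete network's exponent and an estimate of
its total interaction count.

## The degree model

The working model for TF out-degrees (targets bound per TF) is the discrete
power law
$$P(k) = \frac{k^{-\alpha}}{\sum_{j=k_{min}}^{k_{max}} j^{-\alpha}},
\qquad k \in \{k_{min}, \dots, k_{max}\},$$
where the normalizer is a generalized (Hurwitz) zeta sum, evaluated
in-package by Euler–Maclaurin summation to ~1e-13 relative accuracy.
Sampling is by inversion of this exact discrete CDF, never by rounding a
continuous variate: the sampler and the estimator must share one family,
otherwise recovery tests conflate discretization bias with estimation
error.

Smaller $\alpha$ means heavier tails and stronger hub TFs. An unbounded
support requires $\alpha > 1$; where biology supplies a ceiling (a TF
cannot bind more genes than the genome holds) a finite `kmax` is used and
any positive exponent is admissible.

### Exponent estimation

Two estimators are exposed:

* the **exact discrete MLE**, maximizing
  $\ell(\alpha) = -\alpha\sum_i \log k_i - n \log \zeta(\alpha, k_{min})$
  numerically (the default), and
* the **closed-form approximation**
  $\hat\alpha = 1 + n\,[\sum_i \log(k_i / (k_{min} - 1/2))]^{-1}$,
  standard in the scale-free-network literature.

The closed form's error scales with $\alpha - 1$ and fades as $k_{min}$
grows (inside 0.01 by $k_{min} \approx 6$ for $\alpha = 2$, by
$k_{min} \approx 10$ for $\alpha = 3$). The exact MLE is the default
because the minimum-degree scan routinely lands on $k_{min} = 1$, where
the approximation is weakest.

### Minimum-degree selection and goodness-of-fit

Real degree sequences are power-law-like only above some minimum degree.
Every unique degree value that leaves a tail of at least `tail_floor`
observations (default 10, a floor below which the per-candidate fit is
mostly noise) is tried as $k_{min}$; the candidate minimizing the
Kolmogorov–Smirnov distance
$$D = \max_{k \ge k_{min}} |S(k) - P(k)|$$
between the empirical and fitted tail CDFs wins, ties going to the smaller
value. Both CDFs are integer step functions, so the supremum is evaluated
exactly at the observed values and the integers just before them.

The goodness-of-fit p-value is a semiparametric bootstrap: each replicate
keeps the sample size, resamples the below-$k_{min}$ degrees empirically,
draws the tail from the fitted model, and is refitted *with full
minimum-degree re-selection*; $p$ is the fraction of replicates whose $D$
meets or exceeds the observed one (replicates are refitted with a fixed
$k_{min}$ when the caller fixed it, mirroring the original protocol).
Values above 0.1 are read as "the power law is a plausible generator".
Fewer than 100 bootstrap replicates are refused — the p-value resolution
becomes meaningless.

Note that minimum-degree selection trades distribution-level power for
tail focus: on data with an exponential (geometric) body, the scan can
retreat into the far tail where a steep power law fits a small remnant
acceptably, and the bootstrap then has little to reject. Testing whether a
*whole* degree distribution is power-law-like requires fixing
$k_{min} = 1$.

### Model selection

Poisson and discrete-exponential (geometric) alternatives are fitted by
maximum likelihood *left-truncated at the same* $k_{min}$, so
log-likelihoods are comparable observation by observation. Vuong's
closeness test then studentizes the mean pointwise log-likelihood ratio; a
positive statistic with two-sided $p < 0.05$ favors the power law. The
Schwarz/BIC correction for unequal parameter counts is available behind a
flag but off by default (the plain Kullback–Leibler criterion).

**A limitation worth knowing:** against Poisson, the pointwise log-ratio
grows like $\log\Gamma(k)$, so its variance is finite only for
$\alpha > 3$. At smaller exponents a single extreme degree dominates the
variance estimate and the studentized statistic loses power even when the
summed evidence is overwhelming. The package's property tests therefore
exercise Vuong power at $\alpha = 4.12$, where the test's own premises
hold; on heavy-tailed data the statistic should be read qualitatively.

## Inequality analysis

Ranking TFs by increasing out-degree and plotting cumulative target share
against cumulative TF share gives the Lorenz curve; the Gini coefficient
(one minus twice the area under it) summarizes the curve. Equal binding
produces the diagonal; hub-dominated ("capitalistic") networks sag below
it, and the sag decreases as the exponent grows. Curves are evaluated at
every TF rank without binning — observed GRNs have at most a few hundred
TFs, so the exact curve is cheap. Simulated curves default to support
$\{1, \dots, n\}$ and are averaged pointwise across replicates (all
replicates share one rank grid).

## Monte-Carlo inference about complete networks

The extrapolation logic treats the observed out-degrees as a random sample
from the degree population of all genome TFs:

1. **Population**: 10,000 degrees drawn from the fitted (or hypothesized)
   exponent. The population must dwarf any sample drawn from it; 10,000 is
   comfortably above the largest genome TF count considered (~2,500) and
   keeps the central-limit premise intact. The default support cap equals
   the population size.
2. **Sampling distribution**: 1,000 samples of the genome TF count, drawn
   with replacement and each refitted with full minimum-degree
   re-selection — deliberately mirroring what an analyst does to an
   observed network. Re-selection is the dominant variance source: it
   widens the spread well beyond the asymptotic
   $(\alpha - 1)/\sqrt{n}$, particularly at steep exponents where the
   sample holds only a handful of distinct degree values. Degenerate
   samples (a single distinct value) are excluded and counted, never
   silently re-drawn.
3. **Prediction interval**: `center ± 1.96 × SD` at the 95% level by
   default; a percentile construction (central 95% mass of the replicate
   deviations) is always reported alongside, since the normal
   approximation thins out for samples under ~30 nodes — where the
   replicate estimates are visibly skewed and over-dispersed.

### Interaction-count estimation

The observed interaction count is the sum of observed out-degrees. For the
complete network the same sum runs over all $N$ genome TFs, each degree
simulated semiparametrically: with probability $(n - n_{tail})/n$ an
empirical below-$k_{min}$ degree, otherwise a draw from the fitted tail
capped at the genome gene count. This scheme reproduces the observed mean
degree structure by construction, which is exactly what the
self-consistency check requires: at $N = n$ the simulated total must be
statistically indistinguishable (two-sided Z-test) from the observed one.
Coverage of the true total by `mean ± 2 SD` on synthetic complete networks
is the package's recovery check for the extrapolated case. The estimator
presumes a plausible power-law fit; a goodness-of-fit p-value at or below
0.1 aborts unless explicitly overridden.

### When not to extrapolate

Gene-centered assays can leave the out-degree side of a network so
undersampled that the observed exponent anchors nothing. The pipeline
therefore carries a coverage gate (`min_target_coverage`, default 0.5):
when the observed targets cover less than half of the genome's genes, the
predict stage refuses to run rather than produce an interval around an
unreliable exponent. The threshold is a pipeline flag, not a hard-coded
exclusion, so a user who has reason to trust a sparse network can lower
it.

## Subnetwork sampling

Sampling *edges* (not nodes) mimics how GRNs are actually assembled — an
experiment discovers interactions — and never creates degree-zero
singletons. A node's inclusion probability grows linearly with its degree
($1 - (1-p)^{k}$ per-edge independence at proportion $p$), which is why
edge-sampled subnetworks inherit the parent's scale-free shape. The
default draws an exact count (`p·|E|` rounded half-up) without
replacement, keeping replicate sizes identical; Bernoulli sampling is
available behind a flag.

Replicated fits per proportion trace how the exponent spread (SD) grows as
the sampled fraction shrinks; the knee of that SD-versus-proportion curve
— found by exhaustive two-segment least squares, ties to the smaller
abscissa, declared undefined on collinear input — marks the subnetwork
size below which exponent determination degrades. The SD curve is the
default knee input because it is the quantity whose blow-up defines the
breakdown; any other per-size summary can be supplied.

## The in-silico GRN generator

The generator is a static-fitness sampler: the designated TF fraction of
nodes (default 5%, the usual share of TF-coding genes in these genomes)
receives Zipf-type out-fitness $f_j \propto j^{-1/(\alpha-1)}$; each edge
draws its source TF fitness-proportionally and its target uniformly;
duplicate pairs are rejected and re-drawn until exactly the configured
edge count stands. Two design decisions deserve explanation:

* **Fitness-based rather than degree-assignment construction.** Drawing
  each TF's out-degree from the zeta power law and wiring afterwards
  cannot reach realistic scales: 60,000 PDIs across ~265 TFs needs a mean
  out-degree of ~226, while the zeta law at $\alpha = 2$ on any feasible
  support has a mean near 5. The static-fitness construction decouples
  edge count from the exponent and is the standard random-graph model for
  a prescribed expected-degree power law.
* **No finite-size fitness offset.** Offsetting the fitness index (as
  some static power-law generators do to tame hubs) compresses the degree
  range to about one decade at this scale, and an unbounded-support MLE
  on range-truncated data is biased upward by roughly +0.3. With the
  plain Zipf fitness the degree range spans the full node count; the
  duplicate-rejection step itself enforces the biological ceiling (a hub
  cannot bind more targets than there are genes), redistributing the
  excess fitness-proportionally. Fitted exponents then recover the
  configured value, which is what the generator's recovery tests assert.

What the generator deliberately does not emulate: identifier namespaces of
real genomes, assay-specific false-positive structure, tissue composition,
or in-degree architecture (targets are uniform). Passing tests on these
synthetic networks therefore validate the *estimators* under a known
ground truth, not the biological fidelity of any particular network.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit integer seed; there are no
  hidden RNG defaults. Pipeline stages derive per-stage seeds from one
  master seed, and reports embed the configuration hash and seed.
* Zeta sums: direct terms to index 18, Euler–Maclaurin tail with Bernoulli
  corrections through $B_6$; optimizer bracket $(1 + 10^{-6}, 25]$ with
  tolerance $10^{-6}$.
* Quantile inversion precomputes the CDF over the first 65,536 support
  points and binary-searches the zeta CDF beyond, so unbounded-support
  sampling is exact.
* Ties in the two-sample KS test (unavoidable with integer degrees) are
  flagged; the asymptotic p-value is then conservative.
* Degenerate inputs: all-equal degree sequences fall back to
  `kmin = min(degrees)` with a warning; zero-SD sampling distributions
  collapse the prediction interval with a warning; a zero-SD Z-test is
  reported as undefined rather than infinite.

## Problem sizes used in the test suite

The packaged checks run the inference at its study scale — populations of
10,000 degrees, 1,000 Monte-Carlo replicates, 1,000 in-silico networks of
60,000 edges — and the unit suites on reduced synthetic networks (hundreds
to a few thousand edges) chosen so the whole suite completes in minutes
while each property remains sharply testable. Replicate counts in
frequency assertions (20–100) are the smallest that keep the asserted
frequencies stable across seeds.

## Known limitations

* In-degree sequences can be extracted and fitted, but no scale-free claim
  is made for them: gene-centered assays undersample incoming connectivity
  and the package's inference path is built around out-degrees.
* The Vuong test's normal approximation degrades for exponents at or
  below 3 against Poisson (see above).
* The interaction-count estimator inherits the power-law fit; when the
  goodness-of-fit is poor the extrapolation is refused rather than
  repaired.
* Prediction intervals assume the observed exponent is an unbiased
  estimate of the complete network's exponent; violations of that premise
  (systematic assay bias concentrated in particular TF families, say) are
  outside the model.
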