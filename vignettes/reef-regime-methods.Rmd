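---
title: "Methods: regime detection and transition dynamics for reef communities"
author: "reefregimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regime detection and transition dynamics for reef communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefregimes)
```

## The model

A reef *regime* is operationalized here as one component of a multivariate
Gaussian mixture fitted to ten functional-group variables per site: percent
cover of coral, macroalgae, turf algae, crustose coralline algae (CCA) and
other benthic cover, and biomass density (g m^-2^) of browsers, grazers,
scrapers, predators and secondary consumers. Writing $x_i \in
\mathbb{R}^{10}$ for the transformed profile of site $i$, the density is

$$ f(x_i) = \sum_{k=1}^{K} \pi_k \, \phi(x_i \mid \mu_k, \Sigma_k), $$

with mixing weights $\pi_k$, component means $\mu_k$ and covariances
$\Sigma_k$. Before fitting, every variable is fourth-root transformed,
centred, and scaled to unit standard deviation. The fourth root is strong
enough to make one common transformation serviceable for all ten variables —
benthic covers and heavy-tailed fish biomasses alike — which matters because
the mixture model treats all dimensions symmetrically.

Fitting follows the classic model-based clustering recipe:

1. **Hierarchical initialization.** A deterministic agglomerative partition
   (Ward linkage on Euclidean distance, cut at $K$ groups) provides the
   starting hard assignment. Ward linkage is a documented stand-in for
   model-based agglomeration: it optimizes a within-group sum-of-squares
   criterion closely related to the Gaussian likelihood, and — importantly
   for reproducibility — has no random element.
2. **EM.** Expectation-maximization to a relative log-likelihood tolerance
   of $10^{-6}$, capped at 500 iterations. The log-likelihood is asserted
   non-decreasing at every iteration in the test suite.
3. **BIC selection.** Every combination of $K \in \{1, \dots, 9\}$ and six
   covariance structures is fitted and the converged fit with the highest
   $\mathrm{BIC} = 2\log L - p \log n$ (larger is better) wins. The full
   BIC table is always returned so selection can be inspected rather than
   trusted.

The six covariance structures span the spherical/diagonal/full and
equal/varying axes: `spherical-equal`, `spherical-varying`,
`diagonal-equal`, `diagonal-varying`, `full-equal`, `full-varying`. This
deliberately smaller set than the fourteen parameterizations some software
searches keeps the search tractable while still letting BIC trade volume,
shape and orientation freedom against parameter count. $K$ up to 9 brackets
the plausible number of reef regimes with room on both sides.

Assignment uncertainty for an observation is one minus its largest posterior
membership probability, so it lives in $[0, 1 - 1/K]$; argmax ties resolve
to the lowest component index, deterministically.

### Numerical safeguards

Gaussian mixture likelihoods are unbounded: a component can collapse onto a
point (or a flat in some coordinate) and drive its variance to zero. Two
distinct mechanisms handle this:

* a **ridge** of $10^{-6} \times \overline{\mathrm{tr}(\Sigma)/d}$ is added
  to near-singular covariances, and flagged in the fitted model — this
  smooths mild numerical trouble;
* a **degeneracy guard**: any component whose variance in some direction
  falls below $10^{-4}$ of the mean column variance marks the whole fit
  failed, excluding it from BIC selection. This mirrors how mature mixture
  software reports singular fits as missing rather than rescuing them. The
  threshold sits three orders of magnitude below the smallest legitimate
  within-regime variance the synthetic generator can produce (its SD floor,
  see below), so no real candidate is ever rejected.

Without the guard, BIC can favour spurious extra components perched on
point masses — exactly-zero macroalgae or predator values are common in
reef data (and in data generated to resemble it), and a tiny-variance
component on such a spike earns unbounded likelihood while costing only a
few parameters.

## The synthetic generator

The generator is first-class, tested code: it produces datasets with the
statistical structure the analysis assumes, with ground truth, so every
stage can be validated end to end offline.

Its default parameterization encodes a reference five-regime characterization
of Hawaiian forereef communities: per-regime means and standard errors of
all ten functional groups, with per-regime site counts 205, 250, 158, 200
and 214 (1,027 sites; mixing weights are these counts normalized). Raw-scale
standard deviations are reconstructed from standard errors as
$\mathrm{SD} = \mathrm{SE}\sqrt{n_k}$. Sites are drawn on the fourth-root
scale, where each regime is multivariate normal with **diagonal**
covariance; raw-scale SDs map there by the delta method,
$\sigma_t = \mathrm{SD} \cdot m^{-3/4}/4$, with a floor of 0.05 so regimes
with a zero mean (regime 3 has no macroalgae at all) remain proper
components. Negative draws are clamped at zero — clamping, not rejection,
preserves seed reproducibility and speed — and values are raised to the
fourth power to return to the raw scale.

Three conventions deserve explicit statement:

* **Diagonal within-regime covariance is an assumption.** Only means and
  standard errors are available per regime; correlations are not, so
  independence on the transformed scale is the minimal completion. The
  BIC selection is free to choose richer structures, and the recovery tests
  show it correctly identifies diagonal-varying structure on such data.
* **Benthic covers are not forced to sum to 100.** A Gaussian mixture on
  the transformed scale is incompatible with an exact simplex constraint,
  and the reference regime means themselves sum to roughly 98, not 100.
* **The back-transform convention** for reporting a component mean on the
  raw scale is the fourth power of its transformed-scale mean. For
  low-variance cells this is indistinguishable from the raw-scale mean; for
  high-variance cells (regime-2 browsers, $\sigma_t \approx 1.4$) the
  raw-scale *mean* is Jensen-inflated far above the back-transformed mean,
  which behaves more like a median. All recovery claims in this package are
  stated in the back-transformed convention.

`generate_surveys()` decomposes profiles into itemized records the way a
field program would produce them: per-species counts and lengths whose
summed length-weight biomass reproduces each group's density *exactly* (an
integer count at a drawn length plus one closing individual whose length is
solved from the allometric curve), benthic cover lines, a paired-method
calibration subset with a known multiplicative bias, and optionally planted
extreme schooling counts for the outlier-capping stage.
`generate_time_series()` runs a first-order Markov chain per site whose
per-step transition log-probabilities are shifted by per-transition slopes
times two site-level drivers (human population density and thermal stress,
both scaled to [0, 1]) before renormalization.

What the generator does **not** emulate: spatial autocorrelation beyond
island-level coordinate jitter, taxonomic noise (synonyms, misidentification),
observer effects beyond a single multiplicative method bias, and
within-regime correlation between functional groups. Passing tests
therefore demonstrate correctness of the machinery under the stated
statistical assumptions, not robustness to every pathology of real survey
data.

## Harmonization choices

* **Biomass:** $W = a\,\mathrm{TL}^b$ per individual, species-specific
  constants, density = mass/area. Missing parameters are a hard error
  listing the species.
* **Exclusions:** cryptic, nocturnal and pelagic-schooling species plus
  manta rays are dropped from biomass before any aggregation; the packaged
  list is an editable CSV.
* **Outlier capping** is two-step: observations above the global 99.9%
  count quantile identify affected species; those species' counts above
  their own 99.0% quantile (computed on the pre-capping distribution) are
  set to that quantile. Counts, not densities, are screened. Quantiles are
  type-7 (linear interpolation) — the convention must be pinned for
  bit-reproducibility. Re-applying stored thresholds is a fixed point.
* **Calibration** converts source-method densities onto the target-method
  scale by a multiplicative factor, resolved species → family×trophic →
  global (a global factor is always available, so precedence is total). A
  species qualifies with ≥ 10 pairs (evaluated within an island when an
  island column exists); pairs more than 50% zeros switch to a delta model
  (occurrence and positive abundance calibrated separately — 50% is the
  conventional trigger since no cutoff is standard); Shapiro–Wilk at
  α = 0.05 on the through-origin linear fit's residuals decides whether to
  refit log-linearly, and a second failure defers the species to the pooled
  scope. Family×trophic pools are fitted on all pairs of the combination.
  Benthic data are never calibrated.
* **Spatial aggregation** groups sites by single-linkage agglomeration on
  haversine distance cut at 300 m, then averages surveys and years. Single
  linkage is deterministic and order-free, at the cost of chaining: sites
  500 m apart merge if a third sits within 300 m of both. This is the
  documented reading of "surveys within a defined distance".
* **Transform:** fourth root, centre, unit scale; constant columns keep
  scale 1; the state is stored and inverts the transform to machine
  precision, and is reused verbatim at prediction time.
* The depth window (default 0–30 m, forereef) is a metadata filter, so
  sensitivity windows (0–20, 5–20 m) are configuration, not code.

## Community statistics

Ordination (`nmds_ordination`) and dispersion (`dispersion_test`) run on
Bray–Curtis dissimilarities, which require non-negative input; they are
therefore computed on the fourth-root matrix *without* centring or
standardization. This is stated prominently because the clustering runs on
the centred, standardized scale: the two analyses see monotone-related but
not identical geometries.

nMDS minimizes Kruskal stress-1 with monotone regression, best of 50 random
starts under a fixed seed; solutions are unique only up to
rotation/reflection, so determinism is asserted by Procrustes error rather
than coordinate equality. The dispersion test embeds the distance matrix by
principal coordinates, measures distance to group *centroid* (not spatial
median — simpler and documented), and permutes group labels with
$p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_{\mathrm{perm}} + 1)$,
the unbiased estimator, with 999 permutations by default. Univariate
contrasts (depth, complexity, coral richness) use one-way ANOVA with Tukey
HSD family-wise intervals. Coral richness is computed per aggregated site.

## Transitions

Site-year regime predictions are retained when the maximum membership
probability is at least 0.95 and the site has at least three retained
years. Transitions are counted between successive *retained* years, by
default across gaps — multi-year sequences with occasional missing years
are the norm in monitoring data — with a `consecutive_only` switch for the
strict reading. Each cell of the K×K matrix gets a Wilson score interval
on its overall proportion; the Wilson form is used for its small-sample
coverage.

Driver dependence of a transition $i \to j$ is modelled per driver as a
Bernoulli likelihood with $\operatorname{logit} p = \alpha + \beta x$,
$x \in [0, 1]$, fitted only when the transition has at least four
occurrences (fewer return an explicit skip status). Priors are weakly
informative Normal(0, 2.5²) on both coefficients — vague enough to be
dominated by even modest data on the logit scale, proper enough to keep
prior-predictive probabilities off the boundaries. Sampling uses 4 chains
× 2,000 iterations with the first half as warm-up, chain seeds derived
deterministically from one seed; convergence is summarized by split-chain
R-hat. Each driver is fitted separately (the design treats them as separate
hypotheses, and separate fits keep skip rules per-driver).

## Pipeline and reproducibility

`run_pipeline()` chains synthesize → harmonize → cluster → assign → stats →
transitions. One master seed feeds fixed per-stage offsets, so any stage is
reproducible in isolation; the manifest records seeds, per-stage row counts
and MD5 checksums of every output file, and a failed stage leaves completed
outputs plus a `RESUME` marker naming it.

## Problem sizes used in validation

The test suite exercises the full reference design once (1,027 sites, all
54 candidate models) and otherwise uses reduced designs chosen to keep each
property sharply testable: mixing-proportion checks at 10,000 sites;
dispersion type-I calibration with 120 replicate datasets of 30 sites at
999 permutations; driver-model coverage with 40 replicates of 200
transitions (2 chains × 1,000 iterations per fit — interval coverage is
insensitive to chain count); kernel recovery with 200–250 sites over 6–8
years; pipeline runs with 60 sites over 5 years. EM-responsibility oracles
use ≤ 10 points so the brute-force density normalization is itself
trivially verifiable.

## Known limitations

* Regime identity is contingent on the ten chosen variables; adding urchins
  or microbes, say, could split or merge components.
* The mixture is fitted to site means; within-site survey variance is not
  propagated into assignment uncertainty.
* The transition model is first-order and memoryless, with no hidden-state
  smoothing; short noisy series can overstate transition frequencies.
* Drivers enter as per-site scalars; deriving them from rasters (thermal
  stress, population) is outside this package's scope.
* The calibration cascade assumes a multiplicative method bias; additive or
  size-dependent biases would need a different model form.
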