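---
title: "Centroid-standardized isotope vectors: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid-standardized isotope vectors: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsiva)
```

This vignette is the package's account of its own statistics: the model each
estimator assumes, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. The standardization model

Each specimen contributes a pair (δ¹³C, δ¹⁵N) in per mil (δ¹³C vs VPDB,
δ¹⁵N vs air). Within a site, samples are pooled by species and averaged;
the **assemblage centroid** is the *unweighted* mean of those species means.
Weighting by species, not individuals, is deliberate: per-species sample
sizes reflect catchability, not ecology, and an individual-weighted centroid
would be dragged toward whichever species was easiest to catch. The
package's `assemblage_centroid()` enforces this, and a unit test pins the
distinction (10 individuals of one species vs 1 of another must give the
midpoint, not the 10:1-weighted mean).

Every individual then becomes a vector from its local centroid: components
`(dx, dy)`, direction `atan2(dy, dx)` mapped to `[0°, 360°)`, magnitude
`sqrt(dx² + dy²)` in ‰. The angle convention is mathematical — 0° along the
+δ¹³C axis, counterclockwise — chosen because the Cartesian projection used
downstream (X = r·cos μ, Y = r·sin μ) and the way published direction values
pair with their enrichment descriptions are only mutually consistent under
this convention. A specimen exactly on its centroid has magnitude 0 and an
*undefined* direction; such vectors are excluded from circular statistics
with a warning rather than assigned an arbitrary angle.

Two exact invariances follow from the construction and are enforced as
property tests: adding any constant to all of a site's isotope values
changes nothing (translation invariance — this is the point of
standardization), and rotating all displacements about the centroid by φ
rotates every mean direction by φ while leaving r, variance, SD, κ̂, and all
test statistics unchanged (rotation equivariance).

## 2. Circular estimators

Group-level statistics operate on **angles only**. For a set of angles
θ₁…θₙ the resultant of unit vectors gives the mean direction μ and the mean
resultant length r ∈ [0, 1]. Per-individual ‰ magnitudes are reported but
never enter group statistics: this unit-vector convention is what keeps
every Cartesian projection of a group mean inside [−1, 1], which the
downstream positivity shift (+1, Section 3) assumes. The alternative —
magnitude-weighted resultants — would couple the direction summary to the
site-to-site spread of absolute deviations and break that bound.

- **Dispersion**: circular variance 1 − r (exactly; asserted on every
  summary the package produces) and circular SD √(−2 ln r), in degrees,
  infinite at r = 0.
- **Concentration**: κ̂ by the standard piecewise inversion of the Bessel
  ratio (three regimes split at r = 0.53 and 0.85), with the usual
  small-sample bias correction at n ≤ 15 (shrinkage below κ̂ = 2, the
  (n−1)³/(n³+n) factor above). Two quirks are worth knowing. First, the
  corrected estimator is *discontinuous* at the κ̂ = 2 switch, so
  monotonicity of κ̂ in r holds globally only for n > 15; the property test
  asserts it piecewise below that. Second, κ̂ is undefined at n = 1 (the
  reports print "–") and infinite at r = 1 exactly; published tables show
  large finite values for r printed as 1.00 only because r was rounded
  before inversion.
- **Rayleigh's test**: Z = n·r², with the second-order series p-value
  P = e^(−Z)[1 + (2Z − Z²)/(4n) − (24Z − 132Z² + 76Z³ − 9Z⁴)/(288n²)],
  clamped to [0, 1]. The second-order term matters: a singleton sample
  (n = 1, r = 1) gives P = 0.512 under this series but 0.460 at first
  order, and the 0.512 value is what singleton rows in published genus
  tables print. Frozen-value tests pin five further (n, r) → P rows.
- **Rao's spacing test**: U = ½ Σ|Tᵢ − 360/n| over sorted arc gaps
  including the wrap-around; U = 0 for perfectly even spacing and
  360 − 360/n when all angles coincide (both closed forms are tested).
  P-values are reported as brackets between tabulated levels
  ("0.90 > P > 0.50"), the resolution at which U's null distribution is
  classically published. The bracket boundaries here are *Monte Carlo*
  quantiles of the exact null (20,000 uniform samples per n, fixed
  internal seed, cached; the caller's RNG state is untouched): the
  published critical-value table was not available to embed verbatim, and
  a seeded approximation of the same quantiles was judged safer than
  hand-transcribing ~500 constants from memory. A continuous Monte Carlo
  p-value mode (`method = "montecarlo"`, seeded) is also provided.
  Below n = 4 the test is not attempted ("–" in reports).
- **Circular–linear correlation** (direction vs a linear covariate such as
  species richness): R² = (r²ₓc + r²ₓₛ − 2 rₓc rₓₛ r꜀ₛ)/(1 − r²꜀ₛ) with
  rₓc = cor(x, cos θ) etc., and n·R² referred to χ² with 2 df. Whether the
  original analyses used this asymptotic reference or a permutation scheme
  is not documentable; the χ² approximation is the textbook default and is
  validated here by null simulation (independent x gives R² ≈ 0 and
  non-extreme P). The "linear" half of the richness diagnostics is an
  ordinary Pearson correlation between vector *lengths* and the covariate
  — individual ‰ magnitudes in the individual partition, per-site mean
  resultant r in the site partition.

## 3. The two partitions and ancestral reconstruction

Individual-based summaries pool all of a genus's angles across sites;
because sample sizes are usually very uneven across sites, a second
partition first collapses each (genus, site) cell to its mean angle and
summarizes those, one unit vector per occupied site. A genus occupying one
site is then a singleton sample: r = 1, Rayleigh P = 0.512, dispersion
undefined — the reports keep these conventions visible rather than hiding
the rows.

For phylogenetic analysis each genus's (μ, r) is projected to
X = r·cos μ + 1, Y = r·sin μ + 1. X and Y are then reconstructed over
internal nodes **independently**, minimizing Σ (x_parent − x_child)²/ℓ over
branches — squared-change parsimony weighted by branch length, which is the
exact least-squares (and Brownian-motion maximum-likelihood) point
reconstruction. The package solves the stationarity equations directly as a
small linear system rather than iterating a "trace history" algorithm; the
two provably coincide, and the test suite checks the solver against an
independent brute-force minimizer of the same objective on hundreds of
random trees at 10⁻⁸.

Three structural facts are worth making explicit, all enforced as property
tests:

- the estimator is affine-equivariant, so the +1 positivity shift is
  *exactly* neutral — it exists for compatibility with tools that require
  positive character values, not for statistical reasons;
- with equal branch lengths the weighted criterion reduces to unweighted
  squared-change parsimony (the `--unit-lengths` flag reproduces the
  no-branch-length analysis variant);
- every reconstructed internal value lies within the range of its tip
  values.

Zero branch lengths are inadmissible (the criterion divides by ℓ), so
missing or non-positive lengths are replaced by 1 with a logged count —
also the convention for taxa grafted into a tree without length
information. Node angles are recovered by atan2 on the un-shifted
components (full quadrant correction), binned into eight half-open 45°
sectors, and labeled enriched/depleted on each axis by the sign of the
un-shifted component; transition counts are the number of branches whose
endpoints disagree on an axis label.

## 4. The synthetic world

The generator (`simulation_config()` defaults) states one concrete world
and keeps it:

| parameter | default | rationale |
|---|---|---|
| sites | 19 | the scale of a multi-basin field campaign |
| genera | 30 | likewise; ~650 individuals at the defaults |
| occupancy | 0.5/site | gives ≈6 genera per site, matching the density implied by ≈120 genus×site cells over 19 sites |
| individual angles | von Mises(μ_genus, κ = 4) | the circular-normal null of the estimators; κ = 4 ≈ 33° angular SD |
| magnitudes | gamma(shape 2), mean 1.5 ‰ | positive, right-skewed; species deviations span a few ‰ in real biplots |
| centroid jitter | SD 2 ‰ per axis | between-site baseline variation |
| measurement noise | SD 0.15 ‰ | typical mass-spectrometric precision |
| tree | Yule, scaled to unit height | neutral diversification null |
| Brownian rate | 0.05 per unit height | tip SD ≈ 0.22 around a root vector of length 0.5 |
| root state | (X, Y) = (1.5, 1.0) | direction 0°, magnitude 0.5: a definite but not extreme root |

True genus directions default to *evenly spaced* angles. This is not
cosmetic: centroid standardization removes any displacement common to the
whole assemblage, so the generative direction of a genus is recoverable
only when the assemblage's mean species offset is near zero. Evenly spaced
directions make the generative centroid identifiable; phylogenetically
clustered directions (the Brownian-evolved mode, `evolve = TRUE` in
`make_fixture_bundle()`) deliberately produce a world where raw directions
are *not* recoverable — the common component is absorbed into the centroid
— which is itself a documented property of the method, not a bug.

What a green recovery test does establish: the estimation chain from angles
to genus summaries to reconstructed root is unbiased and correctly
calibrated (von Mises recovery at n = 500 within 5°/15%; Rayleigh size
0.05 ± 0.01; root direction within 30° in 20/20 seeded replicates of the
tip-to-root chain). What it does not establish: accuracy at realistic
per-site richness. With ~12 noisy species means per site the estimated
centroid carries a sampling displacement of ~0.4–0.5 ‰, which is a
substantial fraction of a typical 1.3 ‰ individual vector; in the stated
world this drops full-pipeline genus-direction recovery (within 15°) from
~93% of genera under the generative centroids to ~78% under estimated
centroids. The acceptance suite intentionally asserts the stricter
full-pipeline version and documents its failure rather than enlarging the
tolerance or the fixture. Users should read per-genus directions at sites
with few species accordingly.

The generator does **not** attempt isotope biogeochemistry: no basal-source
δ¹³C spectra, no fractionation chains, no covariance between magnitude and
direction, no temporal drift. It emulates the *statistical* structure the
estimators assume, nothing more.

## 5. Numerical and degenerate-input policy

- All internal values are double precision; rounding happens only in
  report writers (angles to integer degrees, r and variance to 2 decimals,
  P to 3 — "0.000" means P < 0.0005, as in the published tables).
- Undefined quantities are `NA` internally and "–" in reports: direction at
  r = 0, concentration at n = 1, dispersion row for singletons, Rao below
  n = 4.
- Significance marks: `*` for Rayleigh P < 0.05, `†` for 0.10 > P ≥ 0.05,
  no multiple-testing correction (matching the convention of the analyses
  this package reproduces).
- Input validation is strict and early: duplicated specimen ids, a species
  mapped to two genera, or a non-numeric isotope cell are errors naming
  the offender; blank isotope cells are dropped with a logged count.
- Degenerate correlation inputs (zero-variance covariate or numerically
  constant lengths) return an explicit undefined flag rather than NaN.
- Config files are JSON rather than YAML (no YAML parser among the
  package's allowed dependencies); flags override file values, and every
  run writes a manifest (inputs, config, checksum, seed, versions).

## 6. Known limitations

- Rao brackets rest on Monte Carlo quantiles (20k replicates): bracket
  boundaries carry simulation error of roughly ±1 quantile step near the
  tabulated levels. The seeded design makes this error fixed and
  reproducible.
- Closed-source legacy software against which the printed tables were
  produced is only reproducible to the rounding of its printed inputs:
  with r given to 2 decimals, SD for r = 0.88 legitimately prints as
  either 28° or 29°.
- The reconstruction returns point estimates only — no confidence
  intervals, no phylogenetic-signal statistics, no tree inference.
- Genus-level operational units follow the input's genus column; the only
  taxonomic surgery offered is the named species-group split
  (`apply_genus_splits()`) and type-species selection when collapsing
  species-level trees (`collapse_to_genera()`).
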