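---
title: "Methods: spatial and circular statistics for bone surface modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial and circular statistics for bone surface modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteotrace)
```

`osteotrace` analyzes bone surface modifications (BSMs) — tooth pits, tooth
scores, cut marks, percussion marks — digitized as 3D points on long-bone
template point clouds. This vignette documents the models and estimators,
the tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the problem left the design open. It states no empirical claim that the test
suite does not itself compute.

## The canonical frame

All coordinates are millimetres in an anatomical frame: x is the
proximo-distal axis, y medio-lateral, z cranio-caudal, with the centroid at
the origin. `canonicalize_template()` obtains this frame as the
eigendecomposition of the point covariance (first principal axis to x,
second to y, third completing a right-handed frame). Two conventions had to
be fixed by us because eigenvectors have arbitrary signs:

- **Sign rule.** Each of the first two eigenvectors is flipped so its
  largest-magnitude component is positive; the third is the cross product.
  This makes canonicalization idempotent and deterministic. There is no
  anatomical information in a bare point cloud to orient "distal vs
  proximal", so the rule is a stable proxy for that convention; plotting
  direction is left to the caller.
- **Dominance test.** A cloud with eigenvalue ratio λ₁/λ₂ < 1.5 (e.g. a
  sphere) has no meaningful long axis and is rejected as degenerate rather
  than silently assigned one. The threshold is a parameter (`min_ratio`).

Crop masks index into the template's point order, so that order is part of
the object's identity: overlap counting is exact set arithmetic, never a
nearest-neighbour match, except when an externally cropped *cloud* is
imported (`match_cloud_crop()`, tolerance 0.5 mm by default, unmatched
points rejected with a report — the tolerance is a knob because matching
misestimates are a known failure mode of overlap-based MNE on heavily
fragmented material).

## Survivorship and MNE

Each specimen's preserved portion is a boolean mask over the template
points. Superimposing masks gives per-point overlap counts (the survivorship
heatmap); the overlap-based MNE is the maximum count. Complete specimens
contribute 1 everywhere, so adding one increments every count and the MNE by
exactly 1 — one of the tested invariants. MNE is reported per (element,
side); cross-side aggregation is deliberately left to the analyst.

## 3D second-order statistics

Marks are treated as a point pattern in a box window W (default: the
template's bounding box padded by 1 mm — a *volumetric* null). The
literature names the functions but not the estimators, so we state them:

- `k3est`: K̂(r) = |W|/(n(n−1)) Σ_{i≠j} 1{d_ij ≤ r} e_ij with translation
  edge correction e_ij = |W| / Π_k (L_k − |Δ_k|). λ² is estimated by
  n(n−1)/|W|², unbiased for binomial (fixed-n) patterns.
- `g3est`: reduced-sample (border) estimator by default,
  Ĝ(r) = #{i : d_i ≤ r, b_i > r} / #{i : b_i > r} with b_i the distance to
  the window boundary; a Kaplan–Meier variant uses b_i as censoring times.
  When the border denominator is empty the value is reported `NA`, never 0.
- `f3est`: empty-space distances from a regular lattice (default spacing:
  shortest window side / 32), border-corrected like G.
- `pcf3est`: ĝ(r) = |W|/(n(n−1)) · (1/4πr²) Σ κ_h(r − d_ij) e_ij with an
  Epanechnikov kernel and Stoyan's bandwidth h = 0.26 λ^(−1/3).

Square-root transforms of K, F, G are variance stabilizers
(`sqrt_version()`, refused for pcf and refused twice). CSR envelopes
(`csr_envelope()`, classical default nsim = 500) condition on the observed n
(binomial simulation, not Poisson), and use pointwise rank envelopes: with
rank 1 the two-sided exceedance probability at a fixed r is 2/(nsim+1) —
the calibration the acceptance suite verifies at nsim = 39.

**Known limitation:** marks live on a 2D surface, but the null is uniform in
the 3D box. Surface-constrained patterns therefore exceed volumetric CSR
envelopes even when they are uniform *on the surface* (the README example
shows this), inflating apparent clustering. Inhomogeneous 3D estimators are
out of scope; interpret envelope exceedances accordingly. The observation
window itself (box vs hull vs surface) is a design freedom; our box default
is validated only through calibration properties.

## Axial profiles and wavelet coherence

Mark positions (linear marks by their midpoint) are normalized by bone
length and binned into `n_units` half-open units (default 50 — the unit
count is not fixed by convention, only "proportional to length"; it is a
parameter everywhere). Profiles of different elements can be concatenated
sequentially for whole-limb comparisons.

`wavelet_coherence()` uses a Morlet mother (ω₀ = 6), dyadic scales
(s₀ = 2Δ, dj = 1/12, truncated at one third of the series length),
coherence R² = |S(W_ab/s)|² / (S(|W_a|²/s) S(|W_b|²/s)) with Gaussian
time-smoothing of width ∝ s and boxcar smoothing over 0.6/dj adjacent
scales, and phase = arg S(W_ab/s) (positive phase: first series leads;
arrows right = in phase, left = anti-phase). Significance is a per-scale
95th-percentile threshold from AR(1) surrogate pairs matched to each
series' lag-1 autocorrelation (default 10,000 surrogate pairs, configurable
down to 100 for tests). AR(1) is the standard surrogate model for this
method; the choice is ours, as is the cone of influence (e-folding time
√2·s of the Morlet). Self-coherence is identically 1 by construction, which
the suite uses as a trivial oracle.

## Embedding and clustering

t-SNE input features are the marks' normalized coordinates only (x by bone
length, y, z by their template extents); mark type and context are carried
as labels, not features — the minimal reading of a feature matrix that was
never stated. Perplexity defaults to ⌈√n⌉ (clipped below n/3 with a
warning), 1000 iterations, exact O(n²) gradient with early exaggeration
(×4, 100 iterations) and momentum 0.5→0.8; exactness keeps runs
deterministic given a seed, and `restarts` returns several runs because the
optimizer is stochastic by design. DBSCAN on the 2D embedding uses eps = 3
and min_pts = 4 (min_pts was unstated; 4 = 2·dim is the textbook default).

## Orientation statistics

Scores are axial (no head or tail): all circular machinery operates on
doubled angles θ = 2φ, and central orientations are reported as
180°-apart pairs wrapped into (−180°, 180°]. Moments follow Fisher's
standardized definitions: R̄, V = 1−R̄, dispersion (1−ρ₂)/(2R̄²), skewness
ρ₂ sin(μ₂−2μ)/(1−R̄)^{3/2}, kurtosis (ρ₂ cos(μ₂−2μ)−R̄⁴)/(1−R̄)².

The angle of a score to the principal axis is acos(|d·a|/‖d‖) mapped to
[0, 180) by a signed in-plane convention: the sign of the score's
perpendicular component against a reference direction (default the
canonical y axis). A convention of this kind is unavoidable — with only a
direction and an axis, 45° and 135° are otherwise indistinguishable — and
it is invariant under joint rotation of scores, axis and reference, and
under endpoint swaps. On a tube, diametrically opposite surface points
mirror the sign, so distributions symmetric about the mean axis (e.g. the
transverse 90° habit) are unaffected while individual angles may reflect;
callers comparing absolute lean directions should pass a surface-aware
reference.

**Rayleigh test.** Z = nR̄², p = exp(−Z)[1 + (2Z−Z²)/(4n) −
(24Z−132Z²+76Z³−9Z⁴)/(288n²)], clipped to [0, 1]. The bracket is an
asymptotic series that turns negative for very large Z; we use the series
whenever the bracket is positive and fall back to the leading exp(−Z) term
otherwise. This rule reproduces all published worked examples we can check,
including one where the bracket exceeds 2 (R̄ = 0.8116, n = 45 → 6.9e−13,
which only the full series gives) and the very-large-Z cells that match
exp(−Z) alone.

**Mardia–Watson–Wheeler.** Pooled doubled angles are ranked (midranks with a
warning under ties), mapped to uniform scores β = 2πr/N, and
W = 2Σ_g (C_g²+S_g²)/n_g is compared against `n_rand` random relabellings
with plus-one correction — a permutation version appropriate for the small,
unbalanced samples typical of wild-context assemblages.

**False positive risk.** FPR converts a p-value to the posterior probability
of a false positive via the Sellke–Bayarri–Berger minimum Bayes factor
BF = −e·p·ln p (valid for p < 1/e, refused otherwise) with a 50:50 prior by
default. The likelihood-ratio variant with stated power is not implemented;
the bound is the defensible default when the original tool's exact formula
is unavailable.

## The synthetic world

`make_template()` samples area-uniform points on a tube with cosine-blended
ellipsoidal flares (epiphysis fraction 0.15 of length). Defaults — 240 mm
femur, 12 mm shaft radius, 28/30 mm epiphyses, 5000 points — are plausible
mid-size cervid proportions; they are *stated world* constants, not tuning
knobs. `sample_scores()` places midpoints uniformly over template points,
draws axial angles from a von Mises on doubled angles (sampling
φ ~ vM(2μ, κ) and halving, the standard axial device), lengths from
lognormal(ln 8, 0.4) mm (no published score lengths exist; ~8 mm median is a
realistic carnivore score), and lays endpoints along the surface geodesic so
they stay on the bone. `sample_matern()` generates Poisson parents in the
window dilated by the cluster radius (avoiding boundary thinning) with
Poisson offspring uniform in balls. `make_crop_set()` attaches the analytic
interval-stabbing number as ground truth.

What the generator does **not** emulate: real cortical geometry (condyles,
trochanters, curvature), anisotropic mark deposition driven by muscle
attachments, mark morphology, or inter-element articulation. A green test
therefore establishes that the estimators and tests are correct on patterns
with known structure — not that any particular taphonomic interpretation of
real material is right.

## Numerical choices and degenerate inputs

- Envelope rank bands require 2·rank ≤ nsim; nsim ≥ 3.
- K(0) = 0; pcf refuses r = 0 (the 1/4πr² factor); empty patterns give
  F ≡ 0; G's empty border denominator yields `NA`.
- Scores with identical endpoints, pits with endpoints, scores without
  endpoints, marks outside the padded template box: all structured errors.
- All generators require an explicit seed; nothing reads ambient RNG state,
  and `derive_seed()` gives every pipeline stage its own 32-bit stream from
  the master seed.
- CSV numerics are written with 9 significant digits; coordinates are
  64-bit mm throughout. Persistence is flat CSV + JSON (diffable,
  round-trippable); a server database is deliberately out of scope.

## Scope decisions

Of the persistence design, the optional single-file SQLite mirror was
dropped: no SQLite driver is guaranteed in the target environment, and the
CSV/JSON dialect already satisfies the round-trip contract the store is
tested against. YAML configs are accepted only as JSON (the YAML subset);
no YAML parser is guaranteed either. Inhomogeneous estimators, cross-type
mark correlation, MNI estimation, fragment refitting and GUI concerns are
out of scope by design.
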