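---
title: "Measuring configurational complexity in complexity spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring configurational complexity in complexity spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexspace)
```

## The model

Many biological systems are built from repeated, homologous parts: thoracic
segments in an arthropod, vertebrae in a spine, worker castes in an ant
colony. `complexspace` treats the *part*, not the species, as the unit of
observation. Every part of every system in a sample is embedded as a point
in one shared morphospace, and each system then becomes a scatter of
points. From that scatter the package extracts three deliberately decoupled
coordinates of configurational complexity:

1. **Part number** `n`: a count of the system's rows in the morphospace.
   Coincident points are distinct parts and count separately.
2. **Degree of differentiation**: the sum of sample variances (SoV) of the
   system's part coordinates across all morphospace axes, reported as the
   median over bootstrap pseudoreplicates. SoV is invariant to rotation and
   translation of the space and scales as $c^2$ under uniform rescaling,
   which is why it is preferred over the orientation-sensitive sum of
   ranges (still available via `sum_of_ranges()`, but never in the default
   profile).
3. **(Ir)regularity of differentiation**: a coefficient of variation (CV,
   sample SD over mean) of inter-part distances. Zero means perfectly
   regular spacing; larger values mean arrangements that need more
   information to describe. It is dimensionless, hence independent of the
   magnitude of differentiation.

The information-theoretic submodule makes the "more information to
describe" intuition concrete on discrete sequences: `shannon_entropy()`
for distributional uncertainty, and `compress_min_rle()`, a dynamic
program that finds the minimal lossless run-length description of a symbol
sequence. A perfectly periodic ten-symbol sequence collapses to seven
characters (`(AB)4CD`); a structureless one stays at ten. Description
length depends on the encoding scheme by construction, so it serves as the
conceptual grounding of the indices, not as a fourth profile axis.

## The regularity dispatch rule

$n$ points can be mutually equidistant only in $n - 1$ or more dimensions
(the vertices of a regular simplex). The regularity index therefore
dispatches on dimensionality:

* `n_axes >= n_parts - 1`: the CV of **all** pairwise distances
  (`all_pairwise`). A regular simplex scores exactly 0.
* otherwise: the CV of the pooled **first- and second-order
  nearest-neighbour distances** (`nnd_1_2`). On a regular square lattice
  these low-order distances are all equal (CV = 0) even though the full
  pairwise distance set is necessarily varied — the case that makes the
  dispatch necessary.

Degenerate inputs are handled explicitly rather than silently: a
single-part system has undefined regularity (recorded as missing, never
0); two parts yield a single distance, whose CV is defined as 0 and
flagged degenerate; fully coincident parts give a 0/0 CV, again recorded
as missing. Coincident duplicates *within* a larger system contribute
legitimate zero distances to the NND pool.

A caveat inherited from the low-order NND construction: it captures
regularity at local scales only, and is insensitive to clustering
structure at larger scales. No remedy is attempted here; multi-scale
spatial statistics are out of scope.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `reps` | `bootstrap_sov()` | 100 | pseudoreplicates, resampled to the system's own part count; the median is reported |
| `seed` | all stochastic ops | required, never defaulted silently | per-system streams are derived by hashing the system id with the master seed (`derive_seed()`), so processing order cannot change results |
| variance convention | everywhere | sample, $n-1$ | stated once, used globally (variances, SDs, CVs) |
| `n_points` | `procrustes_align()` | 200 | resampling density; discretization of the cyclic start-offset search is $2\pi/n$ |
| `H` | EFA | smallest H with cumulative harmonic power ≥ 0.99 (`choose_harmonics()`) | no universally correct harmonic count exists; the power criterion adapts to the shape family and is overridable |
| `center`/`scale.` | `pca_ordinate()` | centre, don't scale | normalized measurements and Fourier coefficients are already commensurate; unit-scaling remains available |

PCA is always computed on the pooled cloud of all parts from all systems —
the shared space is the point of the construction — and the full PC space
is used by default. `subset_axes()` restricts to leading PCs for analyses
that want a 2-D view; retained variance fractions are deliberately not
renormalized, so the subset is honest about what it discarded.

## The outline pipeline

For silhouette data the morphospace axes are elliptical Fourier (EFA)
coefficients:

1. `extract_outline()` traces the 0.5 isolevel around the largest
   8-connected foreground component of a binary mask; holes are ignored.
   Pixel (row $r$, col $c$) maps to Cartesian $(c - 0.5,\; -(r - 0.5))$
   (1-based), and outlines are stored counterclockwise. One fixed
   convention end-to-end avoids accidental mirror-image artefacts in the
   coefficients.
2. `resample_outline()` places vertices at equal arc-length steps.
3. `procrustes_align()` performs generalized Procrustes alignment:
   centring, unit centroid size, rotations only (no reflections), mean
   re-estimated until it moves less than 1e-8 (cap 100 iterations, warning
   on non-convergence). Resampled outlines carry no landmarks, so each
   shape's cyclic start offset is optimised jointly with its rotation when
   fitting the mean; a deterministic max-x-after-centring rule fixes only
   the initial indexing. This makes alignment invariant to how inputs were
   rotated — which a fixed start-vertex rule alone cannot be, since the
   extremal vertex is not a rotation-invariant feature. After convergence
   the whole fit is put into a canonical pose (mean's principal axis along
   x, sense fixed by third moments, shared canonical start index) and the
   mean is seeded from the lexicographically first `source_id`, so results
   are independent of input order.
4. `efa_coefficients()` computes Kuhl–Giardina coefficients of the
   arc-length-parameterized polygon; `flatten_to_morphospace()` turns each
   outline into a $4H$-variable row (DC terms dropped — they encode
   position only), ready for pooled PCA.

No first-harmonic normalization is applied on top of Procrustes by default
(`efa_normalize()` exists for users who want the classical convention):
double normalization would silently re-rotate shapes that were already
aligned.

### Numerical honesty about EFA

Two properties of EFA are easy to over-claim and are documented here
precisely because the tests respect them:

* An ellipse is a single harmonic *in its elliptic parameter*. Under
  arc-length parameterization its eccentricity leaks into higher
  harmonics with amplitude of order $(1 - b/a)/8$. The single-harmonic
  reconstruction check therefore uses a mild ellipse ($b/a = 0.995$, where
  the leakage is far below the 1e-3 relative tolerance); strongly
  eccentric shapes are covered instead by the monotone
  convergence-in-$H$ test.
* Reconstructing a truncated series and re-extracting coefficients is a
  perfect round trip only for constant-speed curves (e.g. a circle, which
  round-trips to ~1e-7). For generic shapes the truncated curve is no
  longer traversed at the speed its coefficients assumed, and coefficients
  drift at the squared relative harmonic amplitude (~1e-3 for a blob with
  15 % shape harmonics). Tests assert exactly these two regimes.
* Shapes with mirror symmetry have two equally optimal aligned poses, and
  rotation-only alignment cannot collapse them; alignment output for such
  shapes is unique only up to the symmetry.

## Synthetic generators as study conditions

All fixtures are generated in code; nothing is downloaded or bundled.

* `simplex_points(n)` and `square_lattice(rows, cols)` are the analytic
  bedrock: configurations whose regularity indices are known exactly
  (0, and 0/positive for the NND/pairwise pair on the lattice).
* `gaussian_system(n, k, sigma)` has expected SoV $k\sigma^2$ (sample
  variance is unbiased), used for Monte-Carlo calibration.
* `synthetic_body()` emulates a two-variable segment table (axial and
  pleural lobe widths). Segments sample a constant-speed circular-arc
  gradient spanning proportional to `differentiation`; positions are a
  convex mixture, weighted by `irregularity`, of equal spacing and sorted
  uniform draws. Sorting matters twice over: real segments keep their
  anteroposterior order, and order statistics keep the spacing response
  monotone across the whole `[0, 1]` range (unsorted placement perturbs
  positions by more than one inter-segment gap already at moderate
  weights, saturating the index). The constant-speed arc ensures
  `irregularity = 0` really is equal spacing *in morphospace*, not just in
  position. Defaults (12 segments, two variables) mirror a typical
  trilobite thorax table. Parameter-recovery tests use 50 systems and are
  desk-scale.
* `synthetic_colony()` produces 3/4/5 superellipse head outlines for
  monomorphic/dimorphic/trimorphic caste structures (males and queens
  plus one to three worker polymorphisms). The superellipse family is an
  arbitrary but convenient closed, smooth, parameter-separable choice;
  caste offsets scale with `shape_sep`, and `shape_sep = 0` collapses the
  colony to identical outlines (downstream SoV exactly 0).

What passing on synthetic data does *not* show: the generators are smooth,
noise-free idealizations. Real masks have pixelation noise, real
measurement tables have observer error, and real caste designations are
partly subjective. Results on such data inherit those uncertainties; the
synthetic suite verifies the algebra and the invariances, not biology.

## Design choices that were genuinely open

* **Run-length cost model**: a literal costs 1; a run `(B)k` costs
  `|B| + 2 + digits(k)`; separators are free; ties go to the literal
  form. This is reverse-engineered from the ten-to-seven worked example —
  no explicit character-accounting rule exists to cite — and is stated as
  such. Runs are not nested: one DP level keeps decoding single-pass and
  suffices for sequences of this kind; nested periodic structure is a
  documented limitation.
* **Pairwise-CV for two parts** is 0 (one distance shows no variation),
  flagged degenerate rather than silently clean.
* **Bootstrap median, not mean**, and resampling to the system's own
  sample size.
* **Full PC space by default** for index computation; the dimensionality
  a study plots is not necessarily the dimensionality it should measure
  in, and truncation is an explicit user action (`subset_axes()`).
* **Simplex construction** projects the n standard basis vectors onto
  their affine span via SVD: exact to rounding, no iterative optimisation.

## Problem sizes

The shipped tests and the acceptance script are desk-scale by design:
simplexes to n = 8, a 4×4 lattice, 50-system recovery experiments with 12
segments each, colonies of 3–5 outlines at 120–200 resampled points, and
exhaustive compression checks over all 9,840 sequences of length ≤ 8 on a
three-letter alphabet. Each block runs in seconds on one CPU; the same
code scales to hundreds of systems unchanged.

## A compact worked example

```{r example, eval = FALSE}
set.seed(1)
tabs <- lapply(1:6, function(i) {
  synthetic_body(10 + i, differentiation = 0.3 * i,
                 irregularity = (i - 1) / 5, seed = 100 + i,
                 system_id = sprintf("sys%02d", i))
})
tab <- part_table(do.call(rbind, lapply(tabs, as.data.frame)))
space <- build_morphospace(normalize_by_system_mean(tab))
cs <- build_complexity_space(space, reps = 100, seed = 42)
cs[, c("system_id", "n_parts", "sov_boot_median", "regularity_cv")]
```

Systems generated with stronger gradients score higher on the
differentiation axis, and systems with more scattered segment positions
score higher on the irregularity axis, while the part-number axis simply
counts rows — three numbers, three decoupled stories.
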