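# complexspace

Tools for quantifying the **configurational complexity** of biological
systems built from repeated, homologous parts — body segments, vertebrae,
limbs, or the worker castes of a social-insect colony. Rather than
collapsing "complexity" into one number, each system is placed in a
*complexity space* whose orthogonal axes are decoupled indices:

1. **Part number** *n* — how many parts the system has;
2. **Differentiation** — how different those parts are from one another,
   measured as the bootstrapped **sum of variances (SoV)** of the system's
   parts in a shared morphospace,
   `SoV = Σ_axes var(coordinates)` (sample variance, median over 100
   pseudoreplicates resampled to the system's own part count);
3. **(Ir)regularity** — how unevenly the parts are spaced, as a
   **coefficient of variation** of inter-part distances: the CV of *all*
   pairwise distances when the morphospace has at least `n − 1` axes
   (mutual equidistance is then geometrically possible, and a regular
   simplex scores exactly 0), otherwise the CV of pooled first- and
   second-order nearest-neighbour distances (0 on a regular square
   lattice).

The morphospace itself can come from per-part measurement tables
(normalized by per-system means) or from binary silhouette masks via an
outline pipeline: boundary tracing → arc-length resampling → generalized
Procrustes alignment → elliptical Fourier analysis → pooled PCA. An
information-theory submodule (Shannon entropy; a minimal run-length
description length found by dynamic programming) grounds the indices in
description-length terms, and seeded synthetic generators (regular
simplexes, lattices, Gaussian clouds, trilobite-like segment tables,
ant-colony-like head outlines) provide analytic test configurations.

## Worked example

Four synthetic segmented bodies with increasing gradient span
(differentiation) and increasingly scattered segment positions
(irregularity):

```r
library(complexspace)

tabs <- lapply(1:4, function(i) {
  synthetic_body(9 + 2 * i, differentiation = 0.4 * i,
                 irregularity = (i - 1) / 3, seed = 100 + i,
                 system_id = sprintf("sys%02d", i))
})
tab   <- part_table(do.call(rbind, lapply(tabs, as.data.frame)))
space <- build_morphospace(normalize_by_system_mean(tab))
cs    <- build_complexity_space(space, reps = 100, seed = 42)
cs[, c("system_id", "n_parts", "sov", "sov_boot_median",
       "regularity_cv", "regularity_method")]
#>   system_id n_parts     sov sov_boot_median regularity_cv regularity_method
#> 1     sys01      11 0.01314         0.01207        0.2671           nnd_1_2
#> 2     sys02      13 0.04274         0.03972        0.4053           nnd_1_2
#> 3     sys03      15 0.11088         0.09743        0.3941           nnd_1_2
#> 4     sys04      17 0.15500         0.15148        0.7590           nnd_1_2
```

Reading the rows: `n_parts` counts segments; `sov_boot_median` climbs with
the built-in differentiation gradient (0.012 → 0.151); `regularity_cv`
rises as segment spacing departs from even (0.27 for equal spacing at this
sample size — the residual comes from the body's end segments — up to 0.76
for strongly scattered positions). With 11–17 parts in a two-axis
morphospace, the dispatch rule selects the nearest-neighbour form
(`nnd_1_2`) throughout.

The same profile is available for outlines (`extract_outline`,
`procrustes_align`, `efa_coefficients`, `flatten_to_morphospace`,
`pca_ordinate`), and on sequences:

```r
s <- symbol_sequence("ABABABABCD")
compress_min_rle(s)$encoded   # "(AB)4CD"  (7 characters, down from 10)
shannon_entropy(s)            # 1.722 bits
```

A command-line interface wraps the same functions
(`inst/cli/complexspace`): subcommands `measure`, `outlines`, `simulate`,
`entropy`, `plot`; every run logs its version, configuration and master
seed, and reruns bit-identically.

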