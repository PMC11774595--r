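Package: complexspace
Title: Complexity Spaces for Systems of Serially Homologous Parts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the configurational complexity of biological systems
    built from repeated, homologous parts (body segments, worker castes,
    vertebrae). Parts are embedded as points in a shared morphospace, built
    either from per-part measurement tables or from binary silhouette masks
    through an outline pipeline (boundary extraction, arc-length resampling,
    generalized Procrustes alignment, elliptical Fourier analysis, principal
    component ordination). Each system is then scored on three decoupled
    complexity axes: number of parts, degree of part differentiation
    (bootstrapped sum of variances) and regularity of that differentiation
    (coefficient of variation of pairwise or of first/second-order
    nearest-neighbour distances). An information-theoretic submodule (Shannon
    entropy and a minimal run-length description length) grounds the indices,
    and seeded synthetic generators provide analytic test configurations,
    trilobite-like segment tables and ant-colony-like head outlines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    lattice,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
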