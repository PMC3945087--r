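Package: slowsubspace
Title: Slow and Independent Subspace Analysis for Complex-Cell Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns complete banks of energy-model complex cells from image
    sequences by optimizing temporal slowness (slow subspace analysis, SSA),
    sparseness (independent subspace analysis, ISA), or a one-parameter
    mixture of the two, using Rosen-style gradient projection on the
    orthogonal group with symmetric (Loewdin) orthogonalization. Includes
    seeded generators for pink-noise stimulus sequences under translation
    (open and cyclic boundaries), rotation, anisotropic scaling and
    composite movie surrogates; DC-projection and symmetric whitening
    preprocessing; evaluation of per-subspace slowness, quadrature phase
    structure, Fourier-basis recovery and filter localization, and the
    slowness-sparseness trade-off curve; plus a spike-triggered-covariance
    analysis of quadratic model neurons derived from slow feature analysis,
    with shuffle-based eigenvalue significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
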