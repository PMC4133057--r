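Package: popcode
Title: Optimal Linear Population Coding for Noisy Sensory Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives the mean-squared-error-optimal linear population code for
    a sensory system in which the environmental signal is blurred, corrupted by
    sensory noise, and encoded by a limited number of noisy neurons.  The
    encoder is obtained in closed form by water-filling power allocation across
    the spectral components of the signal, the decoder is the Wiener filter,
    and a whitening (redundancy-reduction) baseline is provided for comparison.
    The orthogonal degeneracy of the optimal encoder is resolved into concrete
    receptive-field populations by iterative shaping under weight-sparsity,
    response-sparsity, or spatial-locality resource costs, or by orthogonal
    Procrustes projection of Gaussian-bump target populations.  Includes
    synthetic 1/f^2 texture generators, spectral stage diagnostics, and
    receptive-field characterization (half-height centers, tiling, and light
    adaptation metrics) for fovea- and periphery-like cone-to-ganglion-cell
    ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
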