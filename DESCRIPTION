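Package: emgcs
Title: Compressed Sensing Encoding and Reconstruction for EMG-Like Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compressed sensing of surface electromyography and
    similar band-limited biosignals: Bernoulli (+1/-1) measurement encoding,
    orthonormal sparsifying bases (DCT, Haar and Daubechies db4 built as
    periodized filter-bank matrices), and four reconstruction algorithms --
    a normalized projected-gradient l1-minimization solver with an
    incremental sign-change update, orthogonal matching pursuit, compressive
    sampling matching pursuit and normalized iterative hard thresholding.
    Includes an evaluation harness (reconstruction SNR as a function of
    sparsity, compression factor and measurement noise), a synthetic
    EMG-like signal generator, and delimited-text I/O plus a command-line
    interface for running encode/reconstruct/sweep workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
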