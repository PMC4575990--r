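Package: pulsetune
Title: Courtship-Song Stimulus Synthesis, Chaining Behavior Scoring, and
    Calcium-Imaging Tuning-Curve Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis workflow for quantifying how Drosophila courtship
    hearing is tuned to the inter-pulse interval (IPI) of pulse song.
    Provides calibrated synthesis of acoustic stimuli (Gaussian-windowed
    pulse trains, sine song, white noise) and playback protocols; scoring
    of song-induced male chaining behavior (chaining index per 30-s block,
    heat maps, chain fraction); k-means segmentation of calcium-imaging
    movies into ROIs with morphological cleanup; Savitzky-Golay smoothed
    delta-F-over-F peak extraction; IPI and intensity tuning curves with
    per-fly normalization, four-parameter logistic EC50 fits, and a
    neuron-to-neuron transfer function with propagated SEM; and an
    inferential layer with permutation correlation tests, Meng's z-test
    for dependent correlations, and Wilcoxon tests. A synthetic-data
    generator with known ground truth (planted ROIs, GCaMP-like kernels,
    planted IPI/intensity tuning) makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    minpack.lm,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
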