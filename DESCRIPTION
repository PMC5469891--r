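Package: hrv2d
Title: Two-Dimensional LF-HF Analysis of Heart Rate Variability for Stress
    Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain analysis of normal-to-normal (NN) interval
    series for autonomic stress assessment. Implements sliding-window low-
    and high-frequency band powers with Welch spectra, the band-power
    normalization identities and their degeneracy, a family of univariate
    sympathovagal metrics illustrating the ambiguity of the LF/HF ratio, a
    robust instantaneous-amplitude metric based on zero-phase bandpass
    filtering, Hilbert envelopes and per-window trimmed means, and
    two-dimensional LF-HF stress categorization with polynomial-kernel
    support vector machines.  A seeded synthetic tachogram simulator with
    scenario protocols and injectable artifacts (deep breaths, ectopic
    beats, transient bradycardia) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
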