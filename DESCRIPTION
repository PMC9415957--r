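Package: ndentropy
Title: Poincare Plot Nonextensive Distribution Entropy for Univariate Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the complexity of univariate physiological time series
    (EEG, heart rate variability) from the sector-ring occupancy of their
    Poincare plot. Implements classical distribution entropy (Shannon entropy
    of ring-occupancy probabilities) and its nonextensive generalization, in
    which each ring receives a Tsallis nonextensive parameter derived from its
    distance to the origin so that high-amplitude excursions weigh more.
    Includes an exact-covariance fractional Brownian motion simulator for
    validation against the Hurst index, sliding-window analysis with
    parameter-sweep utilities, a sleep-EEG scoring pipeline (singular-spectrum
    detrending, 1-32 Hz zero-phase band-pass, per-epoch scoring) and the
    Jonckheere-Terpstra ordered-trend test with Bonferroni-adjusted pairwise
    comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
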