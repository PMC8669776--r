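Package: multifdr
Title: False Discovery Rate Estimation and Control for Multiple Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-feature false discovery rate (FDR) estimates and
    multiplicity-adjusted p-values for the Benjamini-Hochberg,
    Benjamini-Yekutieli, Bonferroni, Sidak, Holm and Hochberg procedures,
    keeping FDR estimation distinct from FDR control. Includes null-proportion
    (pi0) estimators (fixed value, Last Histogram Height, Storey's smoothed
    lambda estimator, Pounds), a univariate Gaussian lower bound on the FDR, a
    two-group mixture model on the Z scale for empirical-Bayes FDR of tail
    regions, simulation machinery for benchmarking pi0 estimators and the
    realized FDR of control procedures, plain-text input/output, diagnostic
    plots, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, graphics, grDevices, utils, optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
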