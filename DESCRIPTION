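Package: vbcbe
Title: Vector-Based Comparison of Correlated Endpoints in Bioequivalence Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates 2x2 crossover bioequivalence trials from one- and
    two-compartment oral pharmacokinetic models, computes non-compartmental
    endpoints (AUC, AUCinf, Cmax, Tmax, and the average slope of the
    absorption phase), and implements vector-based comparison (VBC) of
    correlated endpoints: endpoints measured across subjects are treated as
    vectors, the angle of each secondary endpoint to a pre-declared anchor
    endpoint is estimated from standardized values, and the secondary
    endpoint is projected onto the axis perpendicular to the anchor before
    the regulatory 90 percent confidence-interval assessment. Includes the
    classical crossover ANOVA with 80-125 percent acceptance limits, Monte
    Carlo power analysis over grids of absorption-rate discrepancy, and
    principal component analysis of the endpoint set.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
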