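Package: soxopt
Title: Stomatal Optimization Based on Xylem Hydraulics (SOX)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and numerical solvers for the SOX stomatal optimization
    model, in which stomatal conductance maximizes the product of leaf
    photosynthesis and normalized xylem hydraulic conductance. Includes the
    xylem vulnerability curve and dynamic plant hydraulic resistance, a
    Collatz-type C3/C4 leaf photosynthesis scheme with JULES-style
    colimitation solved jointly with the stomatal diffusion supply, the
    empirical soil-moisture beta-factor baseline with the Jacobs internal-CO2
    closure, Brooks-Corey soil water retention conversions, a single-bucket
    soil drydown simulator contrasting the two schemes, goodness-of-fit and
    model-selection statistics (RMSE, NSE, AIC) with bounded multistart trait
    calibration and bootstrap uncertainty bands, and seeded synthetic
    generators for trait tables, gas-exchange campaigns and drydown forcing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite, withr
Config/testthat/edition: 3
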