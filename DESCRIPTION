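Package: salmpk
Title: Population Pharmacokinetics of Inhaled Salmeterol and Its Urinary
    Metabolite for Doping-Control Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parent-metabolite population pharmacokinetic model of inhaled
    salmeterol and alpha-hydroxysalmeterol in plasma and urine. Provides a
    closed-form solution of the linear compartmental system with a bladder
    micturition model, log-normal inter-individual variability with athlete
    covariate effects, correlated proportional residual error, and handling
    of below-quantification-limit data (M1, M3, M6). Includes a Monte Carlo
    engine for urine-concentration prediction intervals under permitted and
    prohibited dosing regimens and exceedance of the 10 ng/mL minimum
    reporting level, Laplace-approximated nonlinear mixed-effects estimation
    with MAP Bayesian individual estimates, bootstrap and visual predictive
    checks, and a generator of synthetic pooled multi-study datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
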