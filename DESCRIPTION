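Package: maizecast
Title: Within-Season Maize Yield Forecasting from Climatic Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical within-season forecasting of regional maize yields
    from daily weather and monthly sea-surface-temperature (SST) predictors.
    Implements rainfall-onset detection of the growing season (Dodd-Jolliffe
    criteria), a static 110-day crop calendar with a growing-degree-day split
    into vegetative and reproductive phases, a catalogue of extreme-climate
    and SST indices, AIC-based log-yield detrending, a four-step variable
    selection (zero-variance filter, collinearity filter, LASSO with
    leave-one-year-out cross-validation, correlation cap), per-region
    regression with residual diagnostics, and a two-level leave-one-year-out
    validation with Nash-Sutcliffe efficiency scoring, absolute-yield
    reconstruction and a constant-model baseline. Includes a synthetic-data
    generator (Bernoulli-gamma rainfall, sinusoidal temperature, AR(1) SST
    anomalies, yields from a known linear model) with ground-truth records
    for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    lmtest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
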