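Package: circatime
Title: Circadian Time Prediction from High-Dimensional Oscillatory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Trains sparse predictors of a periodic variable (such as
    circadian time) from high-dimensional measurements like gene
    expression. Each feature's time-dependent mean is estimated with a
    periodic smoothing spline and its noise level from the residuals; a
    penalized matrix decomposition extracts sparse principal components
    of the time-associated variation; the time of a new observation is
    predicted by maximizing a Gaussian log-likelihood over the circle.
    Also provides circular error statistics, a leave-one-group-out
    cross-validation harness, a molecular-timetable comparator method,
    a generator of synthetic oscillatory datasets with known ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
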