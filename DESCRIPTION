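Package: tempmort
Title: Two-Stage Distributed Lag Non-Linear Modelling of Temperature-Attributable Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the mortality burden attributable to
    non-optimum ambient temperature from multi-location daily time series.
    Implements the full two-stage design used in multi-country
    temperature-mortality studies: location-specific quasi-Poisson
    regression with a distributed lag non-linear model (cross-basis of a
    quadratic B-spline in temperature and a natural cubic spline in lag),
    reduction to overall cumulative exposure-response curves, multivariate
    random-effects meta-regression with REML estimation, Wald tests,
    Cochran Q and I2 heterogeneity statistics, best linear unbiased
    predictions, minimum-mortality-temperature search, decomposition of
    attributable deaths into cold/heat and moderate/extreme components,
    and Monte Carlo empirical confidence intervals.  A synthetic-data
    generator with a known exposure-lag-response surface and closed-form
    true attributable fraction supports calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    MASS,
    jsonlite,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
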