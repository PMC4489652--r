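Package: selfexcite
Title: Self-Exciting Contagion Models for Daily Event Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a discrete-day self-exciting (Hawkes-type) point-process
    model to catalogs of rare violent incidents such as mass killings and
    school shootings.  Each event temporarily raises the expected daily
    event count through an exponential-decay kernel parameterised by a
    branching ratio (expected secondary events per index event) and a mean
    contagion duration in days, on top of a flexible baseline (constant,
    linear, or Gaussian-weighted running mean with optional day-of-week and
    seasonal modulation).  Provides maximum-likelihood fitting, profile
    likelihood confidence intervals, likelihood-ratio contagion tests
    calibrated by parametric bootstrap (the contagion duration is absent
    under the null, so chi-squared asymptotics are unreliable), a seeded
    synthetic-catalog generator, Mantel-type spatio-temporal clustering
    tests, and state-level ecological incidence statistics based on the
    binomial cumulative distribution function.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    vegan,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
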