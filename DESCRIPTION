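Package: svyineq
Title: Socio-Economic Inequality in Health from Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to measure and decompose socio-economic inequality in a
    binary health outcome using complex-survey microdata: asset-based wealth
    scores via principal components, population-weighted wealth quintiles and
    weighted fractional ranks, the weighted concentration index and
    concentration curve (overall and by stratum), Wagstaff decomposition of
    the index into per-regressor contributions, weighted descriptive and
    association statistics (prevalence tables, chi-square, Cochran-Armitage
    trend, variance inflation factors, survey-weighted logistic regression),
    and a synthetic two-stage cluster-sample generator with planted,
    quantifiable inequality for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
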