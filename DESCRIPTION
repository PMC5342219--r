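Package: lcscreen
Title: Microsimulation of Lung Cancer Screening Policies in China
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Person-level microsimulation of smoking life-courses and lung
    cancer natural history in the Chinese population, with annual low-dose CT
    screening layered on top. Smoking initiation, cessation and intensity are
    driven by published survey inputs; lung cancer onset follows an
    excess-hazard dose model on pack-years with stage-specific cure and
    survival; screening acts through a stage shift at detection. The model is
    calibrated in stages to smoking prevalence, 2012 lung cancer mortality and
    a trial-based screening-effectiveness anchor, and compares screening
    eligibility rules (U.S. CMS versus the Chinese national guideline) on
    deaths prevented, life-years saved and screening burden over 2016-2050
    under common random numbers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lhs,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
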