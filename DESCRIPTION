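Package: chronOC
Title: Circadian-Aware Modelling and Optimization of Oral Contraceptive Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-timescale model of hormonal contraception coupling a
    delay-differential-equation model of the human menstrual cycle, with
    circadian (cosine) modulation of pituitary gonadotropin synthesis and of
    estradiol and progesterone output, to closed-form two-compartment oral
    pharmacokinetics of ethinyl estradiol (EE) and dienogest (DNG). Provides
    cosinor and pharmacokinetic calibration from hormone and concentration
    time series, constant-dose anovulation screening across clock dosing
    times (dose grids, minimal-dose boundary search, sensitivity scenarios),
    and coevolutionary NSGA-II multi-objective optimization of nonconstant
    21-day regimens that minimize total dose while keeping peak progesterone
    below the 3 ng/mL ovulation-suppression threshold. Synthetic-data
    generators with known ground truth make every calibration stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    lhs,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
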