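Package: brvpbpk
Title: Whole-Body PBPK Modeling of Brivaracetam in Healthy, Cirrhotic and
    Renally Impaired Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A perfusion-limited whole-body physiologically based
    pharmacokinetic (PBPK) model of the antiepileptic drug brivaracetam,
    with saturable CYP2C19 hepatic metabolism, glomerular-filtration-scaled
    renal elimination, and a stomach plus segmented small-intestine oral
    absorption model. Provides Rodgers-Rowland tissue:plasma partition
    coefficients, reference adult physiology with Child-Pugh liver
    cirrhosis and chronic kidney disease scaling, virtual-population
    simulation with visual-predictive-check summaries, non-compartmental
    analysis (Cmax, AUC, terminal slope, clearance), model-evaluation
    statistics (observed/predicted ratios, average fold error, two-fold
    criterion), and a seeded generator of synthetic observed
    concentration-time profiles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
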