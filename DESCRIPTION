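Package: mrdqc
Title: Inter-Laboratory Quality Control for Flow-Cytometric MRD Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quality-control calculus used in multi-centre
    proficiency testing of flow-cytometric minimal residual disease (MRD)
    measurement in acute lymphoblastic leukemia: consensus target votes
    (median of reference or of all submitting laboratories), the x3/:3
    concordance margin, ring-trial outlier flagging (pass/warning/critical),
    diagnostic sensitivity/specificity of positive/negative calls,
    twinning-maturation acceptance rules for trainee laboratories, day-15
    risk-group classification (FLR/FMR/FHR), exact contingency-table tests
    (two-sided Fisher 2x2 and its Freeman-Halton extension to 2xc), and a
    seeded synthetic-data generator with a log-normal reporting-error model
    so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
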