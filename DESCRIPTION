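Package: fcmexposure
Title: Dietary Exposure Assessment for Packaging Migrants in Fatty Cereal Foods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A total-diet-study style pipeline for chemicals that migrate from
    plastic food-contact materials into fatty, cereal-based foods. Quantifies
    target migrants (phthalates, acetyl tributyl citrate, butylated
    hydroxytoluene, octocrylene) in consumption-weighted composite food pools
    from internal-standard-normalised GC-MS responses by the standard-addition
    method, derives recoveries from slope ratios, applies procedural-blank
    subtraction and GEMS/Food-EURO left-censoring (LOQ/2 substitution), and
    computes deterministic mean and 95th-percentile dietary exposures per age
    group from national consumption statistics. Risk is characterised against
    tolerable daily intakes, a cumulative phthalate group-TDI in DEHP
    equivalents, and threshold-of-toxicological-concern (Cramer class)
    screening values. Includes a synthetic measurement-bundle generator with
    known ground truth and regulatory triage of a screening inventory of
    identified packaging migrants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
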