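Package: fishrisk
Title: Dietary Risk Assessment of Organochlorine Contaminants in Fish
    Products
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screening-level dietary risk assessment of organochlorine
    pesticides (OCPs) and polychlorinated biphenyl (PCB) congeners
    measured in fish fillets. Provides censoring-aware handling of
    concentrations reported below the limit of detection, per-species
    summary statistics and metabolite profile shares, Duncan's multiple
    range test for between-species comparisons, lifetime average daily
    dose (LADD) and hazard quotient (HQ) screening against chronic oral
    reference doses, TEF-weighted toxic equivalency (TEQ) for
    dioxin-like PCB congeners, and estimated weekly intake compared with
    former and current tolerable weekly intake (TWI) limits. A seeded
    hierarchical lognormal simulator generates batch-structured,
    left-censored residue data so every pipeline stage is testable
    without raw laboratory measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
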