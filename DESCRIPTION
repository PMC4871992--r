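Package: bdva
Title: Best Documented Visual Acuity Extraction from Ophthalmology EHR Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Rule-based extraction of the best documented Snellen distance
    visual acuity (BDVA) per eye per encounter from the free-text visual
    acuity fields of ophthalmology electronic health record notes. Free-text
    responses are canonicalized and mapped onto a fixed ordinal Snellen
    category scale through a curated vocabulary with a token-scanning
    fallback; the best-ranked category across the defined distance fields is
    returned for each eye. Includes a chart-review style accuracy evaluator,
    an unmapped-response maintenance report, and a deterministic synthetic
    encounter generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
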