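Package: leakyscan
Title: Coevolution of Kozak Context Strength and Downstream AUG Position
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the relationship between the Kozak context
    strength of annotated start codons (sAUG) and the position and reading
    frame of the first downstream AUG (fdAUG) in mRNA transcripts. Provides
    transcript catalog filtering and start-pair annotation, strong/weak
    context decile cohorts with frame and distance statistics, a
    translation-initiation-efficiency selection score (TIESS) over ortholog
    context panels, ribosome-footprint metagene profiling under a
    leaky-scanning initiation model, in-silico tryptic digestion for
    proteoform support, and a synthetic data generator with ground truth
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
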