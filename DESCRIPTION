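Package: studychar
Title: Extraction of Methodological Study Characteristics from NISO-JATS Articles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based extraction of methodological study characteristics from
    NISO-JATS encoded scientific articles. Parses JATS XML into sectioned text
    (introduction, methods, results, discussion, captions), normalizes
    PDF-conversion artefacts, and applies ten heuristic extractors for the
    reported alpha-level, test power, multiple-testing corrections,
    interaction/mediation/moderation effects, test direction, outlier
    definitions in standard deviations, statistical assumptions, analysis
    software, statistical method mentions and the number of reported studies.
    Includes a method-category taxonomy, an article-level
    sensitivity/specificity/accuracy evaluation protocol against gold-standard
    codings, and a synthetic JATS corpus generator with optional
    PDF-conversion-style corruption for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    withr,
    generics,
    ggplot2,
    rlang,
    utils,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
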