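Package: webqual
Title: Quality, Content, and Readability Assessment of Consumer Health Websites
Version: 0.1.0
Authors@R: person("webqual", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Evaluates corpora of patient-facing health websites the way
    structured website-quality studies do: readability scoring from raw text
    (SMOG, Flesch Reading Ease, Flesch-Kincaid grade), DISCERN / JAMA
    benchmark / topic-content instrument scoring with two-rater adjudication
    and third-rater resolution, a normalized weighted composite quality score
    with deterministic ranking, cohort summaries with Kruskal-Wallis
    between-category comparisons, and a synthetic corpus generator with
    controllable reading grade and rater disagreement for end-to-end testing.
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
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
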