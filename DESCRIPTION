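Package: vrikshadx
Title: Rule-Based Diagnosis of Plant Disorders from Vrikshayurvedic Knowledge
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained rule-based expert-system shell for diagnosing
    plant disorders in the Vrikshayurvedic tradition. Ships a declarative
    knowledge base of disorders, yes/no symptom questions and treatments
    (including the classical tridosha split of internal disorders into vata,
    pitta and kapha), a backward-chaining inference engine with answer
    memoization, graded belief tracking and why/how explanation traces, an
    interactive or scripted diagnostic dialogue, and a synthetic-case
    evaluation harness reporting accuracy and confusion under observation
    noise. Results are tibbles throughout, with broom-style tidiers and
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
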