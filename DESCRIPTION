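Package: consortcheck
Title: Sentence-Level CONSORT Reporting Checks for Randomized Controlled Trial Publications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Screens randomized controlled trial (RCT) publications for
    adherence to the CONSORT 2010 reporting checklist. Provides multi-label
    sentence classification with section-header context windows and sentence
    position features, rule-based article-level checks for randomized-trial
    titles (item 1a) and structured abstracts (item 1b), data augmentation for
    rare checklist items (easy data augmentation and LLM prompt builders),
    grouped k-fold cross-validation with sentence- and article-level
    (ANY and 1+) evaluation, McNemar matched-pairs model comparison, and a
    synthetic corpus generator so the whole pipeline is testable without
    external downloads. Includes readers for a documented sentence-level CSV
    corpus schema and JATS-style full-text XML.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
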