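Package: tcmrank
Title: Syndrome-Element Ranking for Traditional Chinese Medicine Cases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks Traditional Chinese Medicine (TCM) syndrome elements for a
    medical case from its symptom fields (engraving symptoms, tongue, moss,
    pulse). Implements a multitask mixture-of-experts ranking network coupled
    to a two-tower matching network through an auxiliary loss, match-score
    feature fusion, and a mimic interaction mechanism, together with
    hand-crafted co-occurrence statistics (bidirectional confidence, lift,
    TF-IDF), a synthetic case-corpus generator with planted symptom-element
    associations, a seeded multi-run training driver, and top-k ranking
    metrics (AUC, RelaImpr, Hits@10, MeanRank, MRR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
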