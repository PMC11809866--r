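Package: safefollow
Title: Harm-Aware Contact Recommendation for Follow-Graph Social Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contact (who-to-follow) recommendation for directed follow
    graphs with explicit protection of vulnerable users. Builds multi-hop
    candidate pools with a harmlessness filtering step, scores candidates by
    network topology (Jaccard similarity and pool occurrence ratio), content
    similarity between normalized topic-interest vectors, and the probability
    output of a harmful-versus-harmless text classifier, and injects a quota
    of pro-recovery accounts into the top-K list. Includes TF-IDF and
    lexicon-based screening classifiers with SMOTE minority oversampling, a
    recommender evaluation suite (precision, recall, mean average precision,
    suggestion- and follow-type ratios, and the average precision-harmlessness
    ratio score), and a seeded synthetic social-graph generator for end-to-end
    testing without access-restricted platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    methods,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    e1071
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
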