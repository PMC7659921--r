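Package: midr
Title: Multi-Interest Dataset Recommendation from Researcher Publications
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based recommendation of repository dataset records
    (modelled on Gene Expression Omnibus series metadata) to researchers,
    using their publication history as the query. Publications and dataset
    metadata are embedded in a shared TF-IDF vector space (unigrams and
    bigrams); a researcher is represented either by a single recency-weighted
    mean vector or, to capture multiple research interests, by one vector per
    publication cluster obtained from a Dirichlet-process multinomial mixture
    sampled by collapsed Gibbs. Includes round-robin merging of per-cluster
    rankings, a relevance threshold that suppresses out-of-scope clusters,
    ranking metrics (NDCG@k, P@k strict/partial), intra-/inter-cluster
    cosine cohesion metrics, a synthetic corpus generator with planted topic
    structure, and a staged command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
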