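Package: contentrec
Title: Knowledge-Based Content Recommendation and Engagement Evaluation
    for Digital Mental Health
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Implements two knowledge-based recommenders for self-guided
    mental-health content cards: a cold-start recommender that ranks cards
    by cosine similarity between a user's onboarding answer vector and
    expert-annotated card label vectors (with category-based diversity
    sampling), and a conversation recommender that scores cards by the
    maximum embedding similarity between coach-user chat messages and card
    descriptions. A routing layer selects the algorithm from user state.
    Also provides the matching evaluation toolkit (majority agreement rate
    with macro-F1, top-K relevance rates by session-length bucket, and
    click/completion engagement rates with demographic stratification) and
    seeded synthetic generators with planted ground truth, including a
    deterministic hashed bag-of-tokens embedding backend, so the full
    pipeline runs end-to-end without any model downloads.
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
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
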