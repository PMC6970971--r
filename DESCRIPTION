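Package: caloscope
Title: Lexicon-Based Caloric Analysis of Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An idiom-aware pipeline for estimating population-level caloric
    intake, caloric expenditure and their ratio from short social-media posts.
    Posts are normalized through a five-step cleaning pipeline (emoticon
    conversion, lowercasing, stopword removal, special-character and number
    stripping), multiword expressions are detected by greedy leftmost-longest
    segmentation so that idiomatic food words ("piece of cake") are excluded
    from caloric counting, posts are classified as food or non-food with
    tf-idf features, and per-region caloric intake (C_in), burn (C_out) and
    ratio (C_rat = C_in/C_out) are aggregated with rankings and
    population-share summaries. A seeded synthetic corpus generator with
    recorded ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    graphics,
    stringi,
    Matrix,
    e1071,
    glmnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
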