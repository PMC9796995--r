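Package: letterfluency
Title: Clustering, Switching and Semantic-Relatedness Scoring for Letter Fluency Tasks
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores letter (phonemic) verbal-fluency transcripts with the two
    families of strategy indices used in clinical neuropsychology: rule-based
    phonological clustering and switching (first-two-phonemes, rhyme,
    vowel-substitution and homonym relations over a CMU-style pronunciation
    lexicon) and a semantic-relatedness index obtained by treating the chain of
    word-embedding turning angles as a discrete worm-like chain and estimating
    its persistence length. Includes readers for minimal CHAT transcripts and
    plain word lists, cohort-level statistics (exclusion rules, descriptive
    tables, Pearson correlation matrices, stepwise multiple regression with
    tolerance/VIF diagnostics), a fully seeded synthetic-cohort generator with
    known ground truth for validation, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
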