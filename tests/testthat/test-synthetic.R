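cfg_small <- function(...) {
  synth_config(n_participants = 8, lexicon_size = 30, embedding_dim = 5,
               seed = 17, ...)
}

test_that("synthetic lexicons plant verifiable relations deterministically", {
  lex <- make_synthetic_lexicon(cfg_small())
  expect_gte(length(lex$words), 30L)
  expect_true(all(startsWith(lex$words, "f")))
  counts <- table(lex$planted_pairs$relation)
  expect_true(all(counts[c("first_two_phonemes", "rhyme", "vowel_swap",
                           "homonym")] >= 3))
  for (i in seq_len(nrow(lex$planted_pairs))) {
    expect_identical(
      pair_relation(lex$planted_pairs$word1[i], lex$planted_pairs$word2[i],
                    lex$pron),
      lex$planted_pairs$relation[i])
  }
  # embeddings are unit norm with the configured dimension
  expect_equal(unname(sqrt(rowSums(lex$emb$vectors^2))),
               rep(1, nrow(lex$emb$vectors)))
  expect_identical(lex$emb$dim, 5L)

  lex2 <- make_synthetic_lexicon(cfg_small())
  expect_identical(lex, lex2)
  expect_error(make_synthetic_lexicon(synth_config(lexicon_size = 19)),
               "lexicon_size")
})

test_that("worm-like-chain angles match the stated law", {
  near0 <- simulate_wlc_angles(1e6, 100, seed = 1)
  expect_true(all(near0 < 1))

  a <- simulate_wlc_angles(5, 1e4, seed = 2)
  expect_true(all(a >= 0 & a <= 180))
  expect_lt(abs(mean(cos(a * pi / 180)) - exp(-1 / 5)) / exp(-1 / 5), 0.02)

  expect_identical(simulate_wlc_angles(3, 50, seed = 9),
                   simulate_wlc_angles(3, 50, seed = 9))
})

test_that("planted cluster structure is recovered exactly by the scorer", {
  config <- cfg_small(error_rate = 0.1, repetition_rate = 0.1)
  lex <- make_synthetic_lexicon(config)
  for (i in 1:10) {
    truth_in <- list(participant_id = paste0("t", i), n_words = 12,
                     true_lp = 3, true_cluster_prob = 0.5)
    s <- simulate_participant(truth_in, lex, config, seed = 100 + i)
    truth <- attr(s, "truth")
    spans <- find_clusters(s$tokens$norm, lex$pron)
    expect_identical(spans[c("start", "end", "size")],
                     truth$planted_spans,
                     label = paste("participant", i))
  }
})

test_that("degenerate clustering probabilities behave as stated", {
  config <- cfg_small(error_rate = 0, repetition_rate = 0)
  lex <- make_synthetic_lexicon(config)
  # cluster_prob 0: semantic steps never pick a phonological relative,
  # so every span is a singleton and NoS = length - 1
  s0 <- simulate_participant(list(participant_id = "a", n_words = 10,
                                  true_lp = 3, true_cluster_prob = 0),
                             lex, config, seed = 5)
  sc0 <- score_phonological(s0, lex$pron)
  expect_identical(sc0$nos, nrow(s0$tokens) - 1L)
  expect_identical(sc0$mcs, 0)
  # no injected errors or repetitions: correct words = distinct productions
  expect_identical(sc0$nocw, length(unique(s0$tokens$norm)))

  # cluster_prob 1: links break only where a word has no relatives
  s1 <- simulate_participant(list(participant_id = "b", n_words = 10,
                                  true_lp = 3, true_cluster_prob = 1),
                             lex, config, seed = 6)
  truth1 <- attr(s1, "truth")
  expect_identical(score_phonological(s1, lex$pron)$nos,
                   nrow(truth1$planted_spans) - 1L)
})

test_that("increasing cluster probability raises MCS and lowers NoS", {
  config <- cfg_small(error_rate = 0, repetition_rate = 0)
  lex <- make_synthetic_lexicon(config)
  run <- function(p, seeds) {
    vapply(seeds, function(sd) {
      s <- simulate_participant(list(participant_id = "x", n_words = 12,
                                     true_lp = 3, true_cluster_prob = p),
                                lex, config, seed = sd)
      sc <- score_phonological(s, lex$pron)
      c(sc$mcs, sc$nos)
    }, numeric(2))
  }
  lo <- run(0.2, 1:40)
  hi <- run(0.8, 1:40)
  expect_gt(mean(hi[1, ]), mean(lo[1, ]))
  expect_lt(mean(hi[2, ]), mean(lo[2, ]))
})

test_that("cohorts are deterministic and carry coupled ground truth", {
  config <- synth_config(n_participants = 12, lexicon_size = 30,
                         embedding_dim = 4, seed = 23,
                         preset = "phonological")
  c1 <- simulate_cohort(config)
  c2 <- simulate_cohort(config)
  expect_identical(c1$sessions, c2$sessions)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_sessions_jsonl(c1$sessions, p1)
  write_sessions_jsonl(c2$sessions, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_length(c1$truths, 12L)
  lp <- vapply(c1$truths, `[[`, numeric(1), "true_lp")
  cp <- vapply(c1$truths, `[[`, numeric(1), "true_cluster_prob")
  expect_lt(cor(lp, cp), 0)  # preset couples clustering against persistence

  empty <- simulate_cohort(synth_config(n_participants = 0, seed = 1))
  expect_length(empty$sessions, 0L)
})

test_that("synthetic inputs round-trip through the standard readers", {
  config <- synth_config(n_participants = 5, lexicon_size = 25,
                         embedding_dim = 3, seed = 31)
  cohort <- simulate_cohort(config)
  dir <- withr::local_tempdir()
  write_synthetic_inputs(cohort, dir)
  expect_true(all(file.exists(file.path(
    dir, c("lexicon.dict", "embeddings.txt", "demographics.csv",
           "truth.csv")))))
  pron <- load_pron_lexicon(file.path(dir, "lexicon.dict"))
  emb <- load_embeddings(file.path(dir, "embeddings.txt"))
  expect_identical(emb$dim, 3L)
  files <- list.files(file.path(dir, "transcripts"), full.names = TRUE)
  expect_length(files, 5L)
  s <- read_plain_list(files[1])
  orig <- cohort$sessions[[which(vapply(cohort$sessions, `[[`, character(1),
                                        "participant_id") ==
                                   s$participant_id)]]
  expect_identical(s$tokens$norm, orig$tokens$norm)
  # written pronunciations reproduce the in-memory lexicon
  expect_identical(pron[[cohort$lexicons$words[1]]],
                   cohort$lexicons$pron[[cohort$lexicons$words[1]]])
})
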