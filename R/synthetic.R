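# Synthetic lexicons, participants and cohorts with known ground truth.
#
# The generator states a small world the scorers can be validated against:
# a pronunciation lexicon with planted pairs for each of the four
# phonological relations, word embeddings placed on a circle so cosine
# angles are controlled, participants who alternate between phonological
# clustering steps (probability cluster_prob) and semantic walk steps whose
# turning angles follow a worm-like chain with a known persistence length,
# and seeded injection of errors and repetitions. Every quantity the
# pipeline estimates has a recorded truth.

#' Synthetic cohort configuration
#'
#' Defaults state the simulated world once: cohort size and measure scales
#' match a typical letter-fluency cohort of people with Alzheimer's disease
#' (47 analysable participants; 1-20 productions per minute; SR roughly in
#' [0.4, 0.8], i.e. persistence lengths of about 1-4.5 segments), with small
#' error and repetition rates. The `"phonological"` preset couples
#' production ability, clustering probability and (inversely) the semantic
#' persistence-length target, reproducing the empirical structure in which
#' participants who switch a lot and cluster phonologically produce more
#' correct words while semantically persistent participants produce fewer.
#'
#' @param n_participants Number of simulated participants.
#' @param lexicon_size Number of target-letter words in the synthetic
#'   lexicon (minimum 20).
#' @param embedding_dim Embedding dimension (>= 2); vectors live on a great
#'   circle of the unit sphere so all cosines are controlled.
#' @param cluster_prob Probability that the next word is drawn from the
#'   current word's planted phonological relatives (scalar; presets draw it
#'   per participant).
#' @param lp_range Interval of true persistence lengths (segments).
#' @param length_lambda Poisson rate for sequence length (lengths are
#'   `1 + Poisson(length_lambda)`, truncated to `max_length`).
#' @param max_length Maximum sequence length.
#' @param error_rate,repetition_rate Per-position injection probabilities.
#' @param target_letter Target letter.
#' @param seed Integer seed; identical configurations reproduce identical
#'   cohorts.
#' @param preset `NULL` or `"phonological"`.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_participants = 47, lexicon_size = 50,
                         embedding_dim = 50, cluster_prob = 0.3,
                         lp_range = c(1, 4.5), length_lambda = 7,
                         max_length = 20, error_rate = 0.05,
                         repetition_rate = 0.05, target_letter = "f",
                         seed = 1L, preset = NULL) {
  stopifnot(lexicon_size >= 20, embedding_dim >= 2,
            cluster_prob >= 0, cluster_prob <= 1,
            all(lp_range > 0), error_rate >= 0, error_rate <= 1,
            repetition_rate >= 0, repetition_rate <= 1)
  if (!is.null(preset)) preset <- match.arg(preset, "phonological")
  structure(list(n_participants = n_participants,
                 lexicon_size = lexicon_size,
                 embedding_dim = embedding_dim,
                 cluster_prob = cluster_prob,
                 lp_range = lp_range,
                 length_lambda = length_lambda,
                 max_length = max_length,
                 error_rate = error_rate,
                 repetition_rate = repetition_rate,
                 target_letter = target_letter,
                 seed = as.integer(seed),
                 preset = preset),
            class = "synth_config")
}

# Phone inventory used to assemble synthetic pronunciations. Intruder
# ("error") words use vowels outside the target-letter inventory so they can
# never rhyme or vowel-swap with a target-letter word.
.synth_vowels <- c("AA", "AE", "EH", "IH", "OW", "UW", "EY")
.synth_cons <- c("B", "D", "G", "K", "L", "M", "N", "P", "R", "S", "T")
.synth_vowel_graph <- c(AA = "o", AE = "a", EH = "e", IH = "i",
                        OW = "oa", UW = "u", EY = "ay")
.synth_error_words <- list(
  dog = c("D", "AO1", "G"), sun = c("S", "AH1", "N"),
  tree = c("T", "R", "IY1"), book = c("B", "UH1", "K"),
  moon = c("M", "IY1", "N"), cup = c("K", "AH1", "P"))

.spell <- function(phones, target_letter) {
  stripped <- sub("[0-2]$", "", phones)
  paste0(target_letter,
         paste(vapply(stripped[-1], function(p) {
           if (p %in% names(.synth_vowel_graph)) .synth_vowel_graph[[p]]
           else tolower(p)
         }, character(1)), collapse = ""))
}

#' Build a synthetic pronunciation + embedding lexicon
#'
#' All words begin with the target letter. At least three word pairs are
#' planted for each of the four phonological relations (shared first two
#' phonemes, rhyme, vowel substitution, homonymy), constructed from a small
#' ARPABET inventory so the relation holds by construction and is verified
#' with [pair_relation()] before returning. Unit-norm embedding vectors are
#' placed at seeded positions on a great circle of the unit sphere in
#' `embedding_dim` dimensions, giving full control over consecutive cosine
#' angles. A handful of intruder words (not starting with the target
#' letter, phonologically unrelatable to any target word) supports error
#' injection.
#'
#' @param config A [synth_config()].
#' @return List of class `synthetic_lexicon`: `pron` (a `pron_lexicon`),
#'   `emb` (an `embedding_lexicon`), `words` (target-letter words),
#'   `error_words`, `planted_pairs` (data frame `word1`, `word2`,
#'   `relation`), `phi` (named circle positions, radians), and `relmat`
#'   (logical any-relation matrix over target words).
#' @export
make_synthetic_lexicon <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$lexicon_size < 20) stop("lexicon_size must be at least 20")
  set.seed(config$seed)
  tl <- config$target_letter
  F0 <- toupper(tl)

  entries <- list()   # spelling -> phone vector
  planted <- list()
  add_word <- function(phones, spelling = NULL) {
    if (is.null(spelling)) spelling <- .spell(phones, tl)
    if (!is.null(entries[[spelling]])) return(NULL)
    entries[[spelling]] <<- phones
    spelling
  }
  plant <- function(w1, w2, relation) {
    planted[[length(planted) + 1L]] <<-
      data.frame(word1 = w1, word2 = w2, relation = relation,
                 stringsAsFactors = FALSE)
  }

  # first_two_phonemes: F V C1 vs F V C2 (same vowel, different coda)
  for (k in 1:3) {
    repeat {
      v <- paste0(sample(.synth_vowels, 1), "1")
      cs <- sample(.synth_cons, 2)
      w1 <- add_word(c(F0, v, cs[1]))
      w2 <- add_word(c(F0, v, cs[2]))
      if (!is.null(w1) && !is.null(w2)) break
    }
    plant(w1, w2, "first_two_phonemes")
  }
  # rhyme: F C1 V C vs F C2 V C (different onset cluster, same tail)
  for (k in 1:3) {
    repeat {
      v <- paste0(sample(.synth_vowels, 1), "1")
      cs <- sample(.synth_cons, 3)
      w1 <- add_word(c(F0, cs[1], v, cs[3]))
      w2 <- add_word(c(F0, cs[2], v, cs[3]))
      if (!is.null(w1) && !is.null(w2)) break
    }
    plant(w1, w2, "rhyme")
  }
  # vowel_swap: F V1 C vs F V2 C (single differing vowel position)
  for (k in 1:3) {
    repeat {
      vs <- paste0(sample(.synth_vowels, 2), "1")
      cc <- sample(.synth_cons, 1)
      w1 <- add_word(c(F0, vs[1], cc))
      w2 <- add_word(c(F0, vs[2], cc))
      if (!is.null(w1) && !is.null(w2)) break
    }
    plant(w1, w2, "vowel_swap")
  }
  # homonym: identical phones, distinct spelling (suffixed variant)
  for (k in 1:3) {
    repeat {
      v <- paste0(sample(.synth_vowels, 1), "1")
      cs <- sample(.synth_cons, 2)
      ph <- c(F0, cs[1], v, cs[2])
      w1 <- add_word(ph)
      w2 <- add_word(ph, spelling = paste0(.spell(ph, tl), "e"))
      if (!is.null(w1) && !is.null(w2)) break
    }
    plant(w1, w2, "homonym")
  }
  # fillers: random F-initial words up to lexicon_size
  guard <- 0L
  while (length(entries) < config$lexicon_size) {
    guard <- guard + 1L
    if (guard > 10000L) stop("phone inventory too small to fill the lexicon")
    len <- sample(2:4, 1)
    phones <- F0
    for (j in seq_len(len)) {
      phones <- c(phones, if (j %% 2 == 1L) {
        paste0(sample(.synth_vowels, 1), if (j == 1L) "1" else "0")
      } else sample(.synth_cons, 1))
    }
    add_word(phones)
  }

  words <- names(entries)
  # write pron lexicon via the standard loader so parsing is exercised
  tmp <- tempfile(fileext = ".dict")
  on.exit(unlink(tmp), add = TRUE)
  all_entries <- c(entries, .synth_error_words)
  writeLines(vapply(names(all_entries), function(w) {
    paste(toupper(w), paste(all_entries[[w]], collapse = " "))
  }, character(1)), tmp)
  pron <- load_pron_lexicon(tmp)

  planted <- do.call(rbind, c(planted, list(make.row.names = FALSE)))
  for (i in seq_len(nrow(planted))) {
    got <- pair_relation(planted$word1[i], planted$word2[i], pron)
    if (got != planted$relation[i]) {
      stop("planted relation failed verification: ", planted$word1[i], "-",
           planted$word2[i], " expected ", planted$relation[i], " got ", got)
    }
  }

  # embeddings: seeded positions on a great circle of the unit sphere
  all_words <- c(words, names(.synth_error_words))
  phi <- stats::runif(length(all_words), 0, 2 * pi)
  phi[seq_along(words)] <-
    sample(seq(0, 2 * pi, length.out = length(words) + 1L)[-(length(words) + 1L)])
  names(phi) <- all_words
  d <- as.integer(config$embedding_dim)
  basis <- qr.Q(qr(matrix(stats::rnorm(d * 2), d, 2)))
  mat <- t(vapply(phi, function(a) {
    as.numeric(basis %*% c(cos(a), sin(a)))
  }, numeric(d)))
  rownames(mat) <- all_words
  emb <- structure(list(vectors = mat, dim = d), class = "embedding_lexicon")

  relmat <- matrix(FALSE, length(words), length(words),
                   dimnames = list(words, words))
  for (i in seq_along(words)) {
    for (j in seq_along(words)) {
      if (i < j) {
        relmat[i, j] <- pair_relation(words[i], words[j], pron) != "none"
        relmat[j, i] <- relmat[i, j]
      }
    }
  }
  diag(relmat) <- TRUE  # a repeated word always chains with itself

  structure(list(pron = pron, emb = emb, words = words,
                 error_words = names(.synth_error_words),
                 planted_pairs = planted, phi = phi, relmat = relmat),
            class = "synthetic_lexicon")
}

#' Simulate worm-like-chain turning angles
#'
#' Draws i.i.d. angles whose expected cosine is exactly `exp(-1 / true_lp)`:
#' heading increments are wrapped Gaussian with variance `2 / true_lp`
#' (the wrapped-normal characteristic function gives
#' `E[cos] = exp(-sigma^2 / 2)` exactly), folded to magnitudes in [0, 180]
#' degrees.
#'
#' @param true_lp True persistence length in segment units (> 0).
#' @param n_angles Number of angles.
#' @param seed Optional seed for reproducibility.
#' @return Numeric vector of angles in degrees.
#' @export
simulate_wlc_angles <- function(true_lp, n_angles, seed = NULL) {
  stopifnot(true_lp > 0, n_angles >= 1)
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(2 / true_lp)
  theta <- stats::rnorm(n_angles, 0, sigma)
  theta <- theta - 2 * pi * round(theta / (2 * pi))  # wrap to (-pi, pi]
  abs(theta) * 180 / pi
}

# One simulated word walk. Clustering steps draw from the current word's
# planted relatives; semantic steps rotate the circle position by a signed
# wrapped-Gaussian increment matched to true_lp and snap to the nearest
# word that is NOT phonologically related to the current one (so planted
# cluster spans are unambiguous by construction).
.simulate_walk <- function(n, lex, cluster_prob, true_lp) {
  words <- lex$words
  phi <- lex$phi[words]
  sigma <- sqrt(2 / true_lp)
  idx <- sample(length(words), 1)
  seq_idx <- idx
  clustered <- logical(0)
  for (step in seq_len(n - 1L)) {
    rel <- which(lex$relmat[idx, ] & seq_along(words) != idx)
    if (stats::runif(1) < cluster_prob && length(rel)) {
      nxt <- if (length(rel) == 1L) rel else sample(rel, 1)
      clustered <- c(clustered, TRUE)
    } else {
      delta <- stats::rnorm(1, 0, sigma)
      target <- (phi[idx] + delta) %% (2 * pi)
      cand <- which(!lex$relmat[idx, ])
      dist <- abs((phi[cand] - target + pi) %% (2 * pi) - pi)
      nxt <- cand[which.min(dist)]
      clustered <- c(clustered, FALSE)
    }
    idx <- nxt
    seq_idx <- c(seq_idx, idx)
  }
  list(words = words[seq_idx], clustered = clustered)
}

# Convert adjacency link flags into span bookkeeping (same convention as
# find_clusters: 1-based inclusive start/end, size = end - start).
.links_to_spans <- function(linked, n) {
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer(), size = integer()))
  }
  starts <- c(1L, which(!linked) + 1L)
  ends <- c(which(!linked), n)
  data.frame(start = starts, end = ends, size = ends - starts)
}

#' Simulate one participant's fluency session
#'
#' Builds a word sequence by alternating phonological clustering steps
#' (probability `truth$true_cluster_prob`) with semantic walk steps whose
#' realised turning angles approximate a worm-like chain with persistence
#' length `truth$true_lp` (exact up to the angular quantisation of the
#' finite lexicon), then injects repetitions (a duplicate of the previous
#' token, which extends its cluster) and errors (an intruder word unrelated
#' to every target word, which always breaks clusters). The ground-truth
#' record, including the planted cluster spans over the final token
#' sequence, is attached as attribute `"truth"`.
#'
#' @param truth List with `participant_id`, `n_words`, `true_lp`,
#'   `true_cluster_prob` and optionally `meta`.
#' @param lexicons A [make_synthetic_lexicon()] result.
#' @param config A [synth_config()].
#' @param seed Optional seed.
#' @return A [fluency_session()] with attribute `"truth"` (fields
#'   `participant_id`, `true_lp`, `true_cluster_prob`, `n_words`,
#'   `planted_spans`).
#' @export
simulate_participant <- function(truth, lexicons, config, seed = NULL) {
  stopifnot(inherits(lexicons, "synthetic_lexicon"),
            inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- truth$n_words
  walk <- .simulate_walk(n, lexicons, truth$true_cluster_prob, truth$true_lp)
  tokens <- walk$words
  linked <- walk$clustered

  # repetitions: duplicate the previous token in place (chains with it)
  i <- 2L
  while (i <= length(tokens)) {
    if (stats::runif(1) < config$repetition_rate) {
      tokens <- append(tokens, tokens[i - 1L], after = i - 1L)
      linked <- append(linked, TRUE, after = i - 2L)
      i <- i + 1L
    }
    i <- i + 1L
  }
  # errors: insert an intruder word, which relates to nothing
  i <- 1L
  while (i <= length(tokens)) {
    if (stats::runif(1) < config$error_rate) {
      err <- sample(lexicons$error_words, 1)
      tokens <- append(tokens, err, after = i)
      pos <- i  # link (i, i+1) becomes FALSE; new link (i+1, i+2) FALSE
      if (pos <= length(linked)) linked[pos] <- FALSE
      linked <- append(linked, FALSE, after = pos - 1L)
      linked <- linked[seq_len(length(tokens) - 1L)]
      i <- i + 1L
    }
    i <- i + 1L
  }
  linked <- linked[seq_len(max(length(tokens) - 1L, 0L))]

  session <- fluency_session(truth$participant_id, tokens,
                             target_letter = config$target_letter,
                             meta = if (is.null(truth$meta)) list() else truth$meta)
  attr(session, "truth") <- list(
    participant_id = truth$participant_id,
    true_lp = truth$true_lp,
    true_cluster_prob = truth$true_cluster_prob,
    n_words = length(tokens),
    planted_spans = .links_to_spans(linked, length(tokens))
  )
  session
}

#' Simulate a full synthetic cohort
#'
#' Draws per-participant generative parameters, simulates every session,
#' and returns sessions, truths and the lexicons. Under the
#' `"phonological"` preset each participant gets an ability score `a` in
#' (0, 1); sequence length scales with `a` (rate `3 + 9 a`), clustering
#' probability is `0.1 + 0.35 a`, and the true persistence length declines
#' from the top to the bottom of `lp_range` as `a` grows (plus noise), so
#' that the cohort shows the empirical pattern: word count correlates
#' positively with switches and negatively with semantic relatedness.
#' Without a preset, `cluster_prob` is the configured scalar and `true_lp`
#' is uniform on `lp_range`. Identical configurations (including seed)
#' reproduce identical cohorts.
#'
#' @param config A [synth_config()].
#' @return List of class `synthetic_cohort`: `sessions` (list of
#'   [fluency_session()]), `truths` (list), `lexicons`
#'   (a `synthetic_lexicon`), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lexicons <- make_synthetic_lexicon(config)
  set.seed(config$seed + 1L)
  np <- config$n_participants
  if (np == 0L) {
    return(structure(list(sessions = list(), truths = list(),
                          lexicons = lexicons, config = config),
                     class = "synthetic_cohort"))
  }
  lo <- config$lp_range[1]
  hi <- config$lp_range[2]
  if (identical(config$preset, "phonological")) {
    ability <- stats::runif(np)
    lambda <- 3 + 9 * ability
    cluster_prob <- 0.1 + 0.35 * ability
    true_lp <- pmin(hi, pmax(lo, hi - (hi - lo) * ability +
                               stats::rnorm(np, 0, 0.3)))
    mmse <- round(pmin(30, pmax(0, 19.1 + 7 * (ability - 0.5) +
                                  stats::rnorm(np, 0, 3))))
  } else {
    ability <- rep(0.5, np)
    lambda <- rep(config$length_lambda, np)
    cluster_prob <- rep(config$cluster_prob, np)
    true_lp <- stats::runif(np, lo, hi)
    mmse <- round(pmin(30, pmax(0, stats::rnorm(np, 19.1, 3.9))))
  }
  n_words <- pmin(config$max_length, 1L + stats::rpois(np, lambda))
  age <- round(pmin(95, pmax(50, stats::rnorm(np, 72.3, 8.6))), 1)
  education <- round(pmin(20, pmax(6, stats::rnorm(np, 11.8, 2.7))))
  seeds <- sample.int(.Machine$integer.max %/% 2L, np)

  sessions <- vector("list", np)
  truths <- vector("list", np)
  for (i in seq_len(np)) {
    truth <- list(participant_id = sprintf("synth%03d", i),
                  n_words = n_words[i],
                  true_lp = true_lp[i],
                  true_cluster_prob = cluster_prob[i],
                  meta = list(age = age[i], education = education[i],
                              mmse = mmse[i]))
    sessions[[i]] <- simulate_participant(truth, lexicons, config,
                                          seed = seeds[i])
    truths[[i]] <- attr(sessions[[i]], "truth")
  }
  structure(list(sessions = sessions, truths = truths, lexicons = lexicons,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort as pipeline input files
#'
#' Emits exactly the formats the pipeline reads: one plain word list per
#' participant under `dir/transcripts/`, a CMU-format pronunciation
#' lexicon, a word2vec-text embedding table, a demographics CSV, and a
#' ground-truth CSV.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_inputs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tdir <- file.path(dir, "transcripts")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions) {
    writeLines(s$tokens$raw, file.path(tdir, paste0(s$participant_id, ".txt")))
  }
  pron <- cohort$lexicons$pron
  writeLines(unlist(lapply(names(pron), function(w) {
    vapply(seq_along(pron[[w]]), function(k) {
      tag <- if (k == 1L) toupper(w) else sprintf("%s(%d)", toupper(w), k)
      paste(tag, paste(pron[[w]][[k]], collapse = " "))
    }, character(1))
  })), file.path(dir, "lexicon.dict"))
  mat <- cohort$lexicons$emb$vectors
  writeLines(c(paste(nrow(mat), ncol(mat)),
               vapply(seq_len(nrow(mat)), function(i) {
                 paste(rownames(mat)[i],
                       paste(format(mat[i, ], digits = 10, scientific = FALSE,
                                    trim = TRUE), collapse = " "))
               }, character(1))),
             file.path(dir, "embeddings.txt"))
  demo <- do.call(rbind, lapply(cohort$sessions, function(s) {
    data.frame(participant_id = s$participant_id,
               age = s$meta$age, education = s$meta$education,
               mmse = s$meta$mmse, stringsAsFactors = FALSE)
  }))
  utils::write.csv(demo, file.path(dir, "demographics.csv"), row.names = FALSE)
  truth <- do.call(rbind, lapply(cohort$truths, function(t) {
    data.frame(participant_id = t$participant_id, n_words = t$n_words,
               true_lp = t$true_lp, true_cluster_prob = t$true_cluster_prob,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
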