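# Phonological clustering and switching (Troyer-style letter-fluency scoring).
#
# Two consecutive words are phonologically related when any of four rules
# holds on their ARPABET pronunciations: shared first two phonemes, rhyme
# (identical from the last stressed vowel), a single vowel substitution, or
# homonymy (identical phones, different spelling). Clusters are maximal runs
# of consecutive related words; transitions between clusters are switches.
# Errors and repetitions take part in clustering but not in the correct-word
# count.

# ARPABET vowel nuclei; stress digits are carried on these symbols.
.arpabet_vowels <- c("AA", "AE", "AH", "AO", "AW", "AY", "EH", "ER", "EY",
                     "IH", "IY", "OW", "OY", "UH", "UW")

.strip_stress <- function(phones) sub("[0-2]$", "", phones)
.is_vowel <- function(phones) .strip_stress(phones) %in% .arpabet_vowels

#' Load a pronunciation lexicon in CMU dictionary format
#'
#' Parses the plain-text CMU Pronouncing Dictionary format: one entry per
#' line, `WORD  PH1 PH2 ...`, comment lines starting `;;;`, pronunciation
#' variants marked `WORD(2)`. Lookup is case-insensitive on normalised forms
#' and all variants are retained.
#'
#' @param path Path to the lexicon file.
#' @return An object of class `pron_lexicon`: a named list mapping each
#'   lowercase word to a list of phone vectors (one per variant).
#' @export
load_pron_lexicon <- function(path) {
  if (!file.exists(path)) stop("cannot read lexicon: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, ";;;")]
  lex <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) < 2L) {
      warning("skipping malformed lexicon line: ", ln)
      next
    }
    word <- tolower(sub("\\(\\d+\\)$", "", parts[1]))
    phones <- toupper(parts[-1])
    if (!all(grepl("^[A-Z]+[0-2]?$", phones))) {
      warning("skipping malformed lexicon line: ", ln)
      next
    }
    lex[[word]] <- c(lex[[word]], list(phones))
  }
  if (!length(lex)) stop("empty pronunciation lexicon: ", path)
  structure(lex, class = "pron_lexicon")
}

#' @export
print.pron_lexicon <- function(x, ...) {
  cat(sprintf("<pron_lexicon> %d words, %d pronunciations\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

.lookup_pron <- function(word, lex) {
  p <- lex[[tolower(word)]]
  if (is.null(p)) list() else p
}

# Tail of the pronunciation from the last stressed vowel (stress 1 or 2);
# falls back to the last vowel when no stress is marked.
.rhyme_tail <- function(phones) {
  stressed <- grepl("[12]$", phones)
  idx <- if (any(stressed)) max(which(stressed)) else {
    v <- which(.is_vowel(phones))
    if (!length(v)) return(NULL)
    max(v)
  }
  .strip_stress(phones[idx:length(phones)])
}

.rule_first_two <- function(p1, p2) {
  length(p1) >= 2L && length(p2) >= 2L &&
    identical(.strip_stress(p1[1:2]), .strip_stress(p2[1:2]))
}

.rule_rhyme <- function(p1, p2) {
  t1 <- .rhyme_tail(p1)
  t2 <- .rhyme_tail(p2)
  !is.null(t1) && !is.null(t2) && identical(t1, t2)
}

# Same phone count, equal everywhere except exactly one position, and the
# differing phones are both vowels.
.rule_vowel_swap <- function(p1, p2) {
  if (length(p1) != length(p2)) return(FALSE)
  s1 <- .strip_stress(p1)
  s2 <- .strip_stress(p2)
  diff <- which(s1 != s2)
  length(diff) == 1L && .is_vowel(p1[diff]) && .is_vowel(p2[diff])
}

.rule_homonym <- function(p1, p2) {
  identical(.strip_stress(p1), .strip_stress(p2))
}

#' Phonological relation between two words
#'
#' Tests the four clustering rules over every pair of pronunciation variants
#' and returns the first match in the precedence order
#' `homonym > first_two_phonemes > rhyme > vowel_swap` (the precedence only
#' affects the reported tag; cluster membership uses any-rule truth).
#' Stress digits are ignored for phone equality. Homonymy additionally
#' requires different spellings: an identical repeated word is a repetition,
#' not a homonym, and is related through `first_two_phonemes`.
#'
#' When a word is missing from the lexicon and `fallback = TRUE` (default),
#' the comparison degrades to a grapheme test: the first two letters of both
#' words stand in for the first two phonemes; rhyme, vowel substitution and
#' homonymy are unavailable without pronunciations.
#'
#' @param w1,w2 Normalised words.
#' @param lex A [load_pron_lexicon()] lexicon.
#' @param fallback Use the grapheme fallback for out-of-lexicon words.
#' @return One of `"homonym"`, `"first_two_phonemes"`, `"rhyme"`,
#'   `"vowel_swap"`, `"none"`.
#' @examples
#' \dontrun{
#' lex <- load_pron_lexicon(system.file("extdata", "cmudict-subset.txt",
#'                                      package = "letterfluency"))
#' pair_relation("find", "fire", lex)   # "first_two_phonemes"
#' pair_relation("fair", "fare", lex)   # "homonym"
#' }
#' @export
pair_relation <- function(w1, w2, lex, fallback = TRUE) {
  w1 <- tolower(w1)
  w2 <- tolower(w2)
  pr1 <- .lookup_pron(w1, lex)
  pr2 <- .lookup_pron(w2, lex)
  if (!length(pr1) || !length(pr2)) {
    if (!fallback) return("none")
    # grapheme route: first two letters of each word stand in for phones
    g1 <- substr(w1, 1L, 2L)
    g2 <- substr(w2, 1L, 2L)
    if (nchar(g1) == 2L && nchar(g2) == 2L && g1 == g2) {
      return("first_two_phonemes")
    }
    return("none")
  }
  pairs <- expand.grid(i = seq_along(pr1), j = seq_along(pr2))
  test_all <- function(rule) {
    for (k in seq_len(nrow(pairs))) {
      if (rule(pr1[[pairs$i[k]]], pr2[[pairs$j[k]]])) return(TRUE)
    }
    FALSE
  }
  if (w1 != w2 && test_all(.rule_homonym)) return("homonym")
  if (test_all(.rule_first_two)) return("first_two_phonemes")
  if (test_all(.rule_rhyme)) return("rhyme")
  if (test_all(.rule_vowel_swap)) return("vowel_swap")
  "none"
}

#' Partition a token sequence into phonological clusters
#'
#' A cluster is a maximal run of consecutive words in which every adjacent
#' pair is phonologically related (chaining); an unrelated word forms a
#' singleton span of size 0. Spans partition the token index range: they are
#' contiguous, non-overlapping and ordered. Cluster size is the word count
#' minus one (two words form a cluster of size 1).
#'
#' @param tokens Character vector of normalised words, in production order.
#'   Errors and repetitions are included by design.
#' @inheritParams pair_relation
#' @return Data frame with 1-based inclusive `start`, `end` indices, `size`,
#'   and an attribute `"relations"` holding the adjacent-pair tags.
#' @export
find_clusters <- function(tokens, lex, fallback = TRUE) {
  n <- length(tokens)
  empty <- data.frame(start = integer(), end = integer(), size = integer())
  if (n == 0L) return(empty)
  rel <- character(0)
  if (n > 1L) {
    rel <- vapply(seq_len(n - 1L), function(i) {
      pair_relation(tokens[i], tokens[i + 1L], lex, fallback)
    }, character(1))
  }
  linked <- rel != "none"
  starts <- c(1L, which(!linked) + 1L)
  ends <- c(which(!linked), n)
  spans <- data.frame(start = starts, end = ends, size = ends - starts)
  attr(spans, "relations") <- rel
  spans
}

#' Mean cluster size (MCS)
#'
#' Total cluster size divided by the number of clusters; singleton spans
#' (size 0) count in the denominator, so a sequence of entirely unrelated
#' words has MCS 0.
#'
#' @param spans Data frame from [find_clusters()].
#' @return A number, or `NA` for an empty span list.
#' @export
mean_cluster_size <- function(spans) {
  if (nrow(spans) == 0L) return(NA_real_)
  sum(spans$size) / nrow(spans)
}

#' Number of switches (NoS)
#'
#' Transitions between consecutive clusters: one fewer than the number of
#' spans, and 0 for an empty or single-span sequence.
#'
#' @inheritParams mean_cluster_size
#' @return Non-negative integer.
#' @export
count_switches <- function(spans) {
  max(nrow(spans) - 1L, 0L)
}

#' Score the phonological strategy of a session
#'
#' Runs cluster detection over the full token sequence (errors and
#' repetitions included) and reports NoCW, MCS and NoS together with a
#' per-token audit table.
#'
#' @param session A [fluency_session()].
#' @inheritParams pair_relation
#' @return List with `nocw`, `mcs`, `nos`, `spans` and `audit` (data frame
#'   with token, span id and relation to the previous token).
#' @export
score_phonological <- function(session, lex, fallback = TRUE) {
  stopifnot(inherits(session, "fluency_session"))
  toks <- session$tokens$norm
  spans <- find_clusters(toks, lex, fallback)
  span_id <- integer(length(toks))
  for (k in seq_len(nrow(spans))) {
    span_id[spans$start[k]:spans$end[k]] <- k
  }
  rel_prev <- if (length(toks)) {
    c(NA_character_, attr(spans, "relations"))
  } else {
    character(0)
  }
  audit <- data.frame(
    index = seq_along(toks),
    token = toks,
    span = span_id,
    relation_to_prev = rel_prev,
    stringsAsFactors = FALSE
  )
  list(nocw = count_correct_words(session),
       mcs = mean_cluster_size(spans),
       nos = count_switches(spans),
       spans = spans,
       audit = audit)
}
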