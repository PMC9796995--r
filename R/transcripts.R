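# Reading and normalising letter-fluency transcripts.
#
# A session is the unit of analysis: one participant's ordered word
# productions in a timed letter-fluency trial (default: letter "f", 60 s),
# plus optional demographics.

#' Construct a fluency session
#'
#' A `fluency_session` holds one participant's ordered token sequence for a
#' timed letter-fluency trial, together with per-token annotations
#' (normalised form, repetition flag, error flag) and optional demographics.
#'
#' @param participant_id Opaque participant identifier.
#' @param raw Character vector of tokens as transcribed, in production order.
#' @param target_letter Single lowercase letter the trial targets.
#' @param duration_s Trial duration in seconds.
#' @param meta Named list with optional `age`, `education`, `mmse`.
#' @return An object of class `fluency_session`: a list with `participant_id`,
#'   `tokens` (data frame with columns `raw`, `norm`, `is_repetition`,
#'   `is_error`), `target_letter`, `duration_s` and `meta`.
#' @examples
#' s <- fluency_session("p1", c("Fish", "fox", "fish"))
#' count_correct_words(s)
#' @export
fluency_session <- function(participant_id, raw = character(),
                            target_letter = "f", duration_s = 60,
                            meta = list()) {
  stopifnot(is.character(raw), length(target_letter) == 1L,
            grepl("^[a-z]$", target_letter), duration_s > 0)
  if (!is.null(meta$mmse) && !is.na(meta$mmse) &&
      (meta$mmse < 0 || meta$mmse > 30)) {
    stop("mmse must lie in [0, 30]")
  }
  norm <- normalize_token(raw)
  keep <- nzchar(norm)
  raw <- raw[keep]
  norm <- norm[keep]
  tokens <- data.frame(
    raw = raw,
    norm = norm,
    is_repetition = duplicated(norm),
    is_error = !startsWith(norm, target_letter),
    stringsAsFactors = FALSE
  )
  structure(
    list(participant_id = as.character(participant_id), tokens = tokens,
         target_letter = target_letter, duration_s = duration_s, meta = meta),
    class = "fluency_session"
  )
}

#' @export
print.fluency_session <- function(x, ...) {
  cat(sprintf("<fluency_session> %s: %d tokens (letter '%s', %gs)\n",
              x$participant_id, nrow(x$tokens), x$target_letter, x$duration_s))
  if (nrow(x$tokens)) {
    cat(" ", paste(utils::head(x$tokens$norm, 12L), collapse = " "),
        if (nrow(x$tokens) > 12L) "..." else "", "\n")
  }
  invisible(x)
}

#' Normalise a transcribed token
#'
#' Lowercases and strips leading/trailing punctuation while keeping internal
#' hyphens and apostrophes (so items like "fire-fly" survive intact).
#' Idempotent: applying it twice equals applying it once.
#'
#' @param x Character vector of raw tokens.
#' @return Character vector of normalised forms (possibly empty strings).
#' @export
normalize_token <- function(x) {
  x <- tolower(x)
  x <- sub("^[^[:alnum:]]+", "", x)
  sub("[^[:alnum:]]+$", "", x)
}

#' Read a plain one-word-per-line transcript
#'
#' @param path Path to a UTF-8 text file, one token per line; blank lines are
#'   ignored.
#' @param target_letter Target letter of the trial.
#' @param participant_id Identifier; defaults to the file name without
#'   extension.
#' @return A [fluency_session()].
#' @export
read_plain_list <- function(path, target_letter = "f",
                            participant_id = NULL) {
  if (!file.exists(path)) stop("cannot read transcript: ", path)
  if (is.null(participant_id)) {
    participant_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  fluency_session(participant_id, lines[nzchar(lines)], target_letter)
}

# CHAT terminator / code tokens dropped during parsing.
.chat_drop <- c(".", "?", "!", "+...", "+..?", "+/.", "+//.", "+.",
                "xxx", "yyy", "www")

#' Read a minimal-dialect CHAT transcript
#'
#' Extracts tokens from participant tiers (lines beginning `*PAR:`, including
#' their tab-indented continuation lines) of a TalkBank CHAT file.
#' Investigator (`*INV:`) and dependent (`%`) tiers are ignored. The dialect
#' is deliberately minimal: utterance terminators and `+...`-style codes are
#' dropped, `[x N]` repetition marks expand the preceding token (or `<...>`
#' group) N times, remaining bracketed annotations are removed, and `&`-prefixed
#' filler codes are discarded. Overlap and retracing codes of the full CHAT
#' grammar are out of scope.
#'
#' @inheritParams read_plain_list
#' @return A [fluency_session()]; a file with no participant tier yields an
#'   empty session (zero tokens), not an error.
#' @export
read_chat_session <- function(path, target_letter = "f",
                              participant_id = NULL) {
  if (!file.exists(path)) stop("cannot read transcript: ", path)
  if (is.null(participant_id)) {
    participant_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  text <- character()
  in_par <- FALSE
  for (ln in lines) {
    if (startsWith(ln, "*PAR:")) {
      text <- c(text, sub("^\\*PAR:\\s*", "", ln))
      in_par <- TRUE
    } else if (in_par && startsWith(ln, "\t")) {
      text <- c(text, trimws(ln))
    } else if (grepl("^[*%@]", ln)) {
      in_par <- FALSE
    }
  }
  fluency_session(participant_id, .parse_chat_tokens(paste(text, collapse = " ")),
                  target_letter)
}

# Expand [x N] repetition marks, strip other bracketed codes and CHAT
# terminators; returns the raw token vector in production order.
.parse_chat_tokens <- function(text) {
  # <a b> [x 3] -> the group repeated 3 times
  rep_group <- gregexpr("<([^<>]*)>\\s*\\[x\\s*(\\d+)\\]", text, perl = TRUE)
  text <- .expand_matches(text, rep_group[[1]],
                          function(m) {
                            g <- sub("^<([^<>]*)>.*$", "\\1", m)
                            n <- as.integer(sub(".*\\[x\\s*(\\d+)\\].*", "\\1", m))
                            paste(rep(trimws(g), n), collapse = " ")
                          })
  # word [x 3] -> the word repeated 3 times
  rep_word <- gregexpr("(\\S+)\\s*\\[x\\s*(\\d+)\\]", text, perl = TRUE)
  text <- .expand_matches(text, rep_word[[1]],
                          function(m) {
                            w <- sub("^(\\S+)\\s*\\[.*$", "\\1", m)
                            n <- as.integer(sub(".*\\[x\\s*(\\d+)\\].*", "\\1", m))
                            paste(rep(w, n), collapse = " ")
                          })
  text <- gsub("\\[[^][]*\\]", " ", text)   # remaining bracketed annotations
  text <- gsub("[<>]", " ", text)           # scope markers, content kept
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[!toks %in% .chat_drop]
  toks[!startsWith(toks, "&") & !startsWith(toks, "+")]
}

.expand_matches <- function(text, m, f) {
  if (length(m) == 1L && m[1] == -1L) return(text)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  out <- character()
  last <- 1L
  for (i in seq_along(starts)) {
    out <- c(out, substr(text, last, starts[i] - 1L),
             f(substr(text, starts[i], starts[i] + lens[i] - 1L)))
    last <- starts[i] + lens[i]
  }
  paste0(paste(out, collapse = " "), " ", substr(text, last, nchar(text)))
}

#' Re-apply error annotation to a session
#'
#' A token is an error iff its normalised form does not begin with the
#' session's target letter. This is the only objective rule available from a
#' transcript alone; protocol-specific rules (proper nouns, morphological
#' variants) are not applied. The operation is idempotent.
#'
#' @param session A [fluency_session()].
#' @return The session with `is_error` flags recomputed.
#' @export
annotate_errors <- function(session) {
  stopifnot(inherits(session, "fluency_session"))
  session$tokens$is_error <-
    !startsWith(session$tokens$norm, session$target_letter)
  session
}

#' Count correct words (NoCW)
#'
#' Tokens flagged as errors or repetitions are excluded from the count; they
#' still participate in cluster and switch scoring.
#'
#' @param session A [fluency_session()].
#' @return Non-negative integer.
#' @export
count_correct_words <- function(session) {
  stopifnot(inherits(session, "fluency_session"))
  sum(!session$tokens$is_error & !session$tokens$is_repetition)
}

#' Read a demographics table
#'
#' @param path CSV with columns `participant_id` and any of `age`,
#'   `education`, `mmse`; missing cells allowed.
#' @return A data frame keyed by `participant_id`.
#' @export
read_demographics <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(d)) {
    stop("demographics file must have a participant_id column")
  }
  d$participant_id <- as.character(d$participant_id)
  bad <- !is.na(d$mmse) & (d$mmse < 0 | d$mmse > 30)
  if (!is.null(d$mmse) && any(bad)) {
    warning("mmse outside [0, 30] set to NA for ",
            sum(bad), " participant(s)")
    d$mmse[bad] <- NA
  }
  d
}

#' Attach demographics to sessions
#'
#' @param sessions List of [fluency_session()] objects.
#' @param demographics Data frame from [read_demographics()].
#' @return The session list with `meta` fields filled where ids match.
#' @export
attach_demographics <- function(sessions, demographics) {
  for (i in seq_along(sessions)) {
    row <- demographics[demographics$participant_id ==
                          sessions[[i]]$participant_id, , drop = FALSE]
    if (nrow(row) == 1L) {
      for (f in intersect(c("age", "education", "mmse"), names(row))) {
        sessions[[i]]$meta[[f]] <- row[[f]]
      }
    }
  }
  sessions
}

#' Serialise sessions to JSON lines
#'
#' One JSON record per participant; [read_sessions_jsonl()] inverts it.
#'
#' @param sessions List of [fluency_session()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions_jsonl <- function(sessions, path) {
  lines <- vapply(sessions, function(s) {
    jsonlite::toJSON(list(
      participant_id = s$participant_id,
      target_letter = s$target_letter,
      duration_s = s$duration_s,
      meta = s$meta,
      tokens = s$tokens
    ), auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sessions_jsonl
#' @export
read_sessions_jsonl <- function(path) {
  lapply(readLines(path, warn = FALSE), function(ln) {
    rec <- jsonlite::fromJSON(ln)
    raw <- if (length(rec$tokens)) rec$tokens$raw else character()
    s <- fluency_session(rec$participant_id, raw,
                         target_letter = rec$target_letter,
                         duration_s = rec$duration_s,
                         meta = as.list(rec$meta))
    s
  })
}
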