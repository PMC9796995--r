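# Semantic-relatedness index for letter-fluency word sequences.
#
# Each produced word is mapped to an embedding vector; the arccos of the
# cosine similarity between consecutive word vectors gives a turning angle
# in [0, 180] degrees. The ordered angles are read as the bending angles of
# a discrete chain of unit segments (the picture used for DNA and polymer
# backbones), whose persistence length Lp measures how far the semantic
# "direction" persists: <cos theta(s)> = exp(-s / Lp). The bounded index
# SR = max(0, mean adjacent cosine) = exp(-1/Lp) under that law.

#' Load word embeddings in word2vec/GloVe text format
#'
#' Accepts the plain-text format with or without the `"<count> <dim>"` header
#' line: each row is a word followed by `d` floats. Duplicate words keep the
#' first occurrence (with a warning); zero vectors are skipped (cosine would
#' be undefined). Lookup is case-insensitive.
#'
#' @param path Path to the embeddings file.
#' @return An object of class `embedding_lexicon`: a list with `vectors`
#'   (numeric matrix, one row per word) and `dim`.
#' @export
load_embeddings <- function(path) {
  if (!file.exists(path)) stop("cannot read embeddings: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty embeddings file: ", path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))) {
    lines <- lines[-1]  # "<count> <dim>" header
  }
  parts <- strsplit(trimws(lines), "\\s+")
  dims <- lengths(parts) - 1L
  if (length(unique(dims)) != 1L) {
    stop("inconsistent embedding dimensions in ", path, ": ",
         paste(unique(dims), collapse = ", "))
  }
  d <- dims[1]
  if (d < 2L) stop("embedding dimension must be >= 2, got ", d)
  words <- tolower(vapply(parts, `[`, character(1), 1L))
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (anyNA(mat)) stop("non-numeric embedding values in ", path)
  zero <- sqrt(rowSums(mat^2)) == 0
  if (any(zero)) {
    warning("skipping ", sum(zero), " zero vector(s) in ", path)
    mat <- mat[!zero, , drop = FALSE]
    words <- words[!zero]
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warning("duplicate embedding entries for: ",
            paste(unique(words[dup]), collapse = ", "),
            " (keeping first occurrence)")
    mat <- mat[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  rownames(mat) <- words
  structure(list(vectors = mat, dim = d), class = "embedding_lexicon")
}

#' @export
print.embedding_lexicon <- function(x, ...) {
  cat(sprintf("<embedding_lexicon> %d words, dimension %d\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Turning angles between consecutive word vectors
#'
#' For each adjacent pair of in-vocabulary words, the angle (degrees, in
#' [0, 180]) is the arccos of their cosine similarity; the cosine is clipped
#' to [-1, 1] before arccos. Out-of-vocabulary words are dropped from the
#' sequence (and reported), not zero-vectored. Repeated words are kept: a
#' repetition contributes a 0-degree angle, which is the intended semantics
#' (a repeated word is maximally related to itself).
#'
#' @param words Character vector of produced words in order.
#' @param emb An [load_embeddings()] lexicon.
#' @return An object of class `angle_sequence`: list with `angles_deg`,
#'   `words_used`, `oov_words` and `status` (`"ok"` or
#'   `"insufficient_data"` when fewer than two words are in vocabulary).
#' @export
turning_angles <- function(words, emb) {
  stopifnot(inherits(emb, "embedding_lexicon"))
  words <- tolower(words)
  in_vocab <- words %in% rownames(emb$vectors)
  oov <- words[!in_vocab]
  used <- words[in_vocab]
  if (length(used) < 2L) {
    return(structure(list(angles_deg = numeric(0), words_used = used,
                          oov_words = oov, status = "insufficient_data"),
                     class = "angle_sequence"))
  }
  v <- emb$vectors[used, , drop = FALSE]
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1L, , drop = FALSE]
  cosine <- rowSums(a * b) /
    (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  cosine <- pmin(1, pmax(-1, cosine))
  structure(list(angles_deg = as.numeric(acos(cosine) * 180 / pi),
                 words_used = used, oov_words = oov, status = "ok"),
            class = "angle_sequence")
}

#' @export
print.angle_sequence <- function(x, ...) {
  cat(sprintf("<angle_sequence> %d angles (%s)\n",
              length(x$angles_deg), x$status))
  if (length(x$angles_deg)) {
    cat(" ", paste(sprintf("%.1f°", utils::head(x$angles_deg, 10L)),
                   collapse = " - "), "\n")
  }
  invisible(x)
}

.as_angles <- function(angles) {
  if (inherits(angles, "angle_sequence")) angles <- angles$angles_deg
  stopifnot(is.numeric(angles), all(angles >= 0 & angles <= 180))
  angles
}

#' Build the 2D chain diagram for an angle sequence
#'
#' Unit-length segments start at the origin heading along +x; at joint `i`
#' the heading rotates by `angles_deg[i]`, signed according to `sign_rule`.
#' The chain is a visualisation and geometry-testing device only: the
#' semantic-relatedness index never depends on the sign rule, because the
#' cosine determines only the angle magnitude.
#'
#' @param angles An `angle_sequence` or a numeric vector of degrees in
#'   [0, 180].
#' @param sign_rule `"positive"` (all turns one way, default),
#'   `"alternating"`, or `"random"` (seeded, for wandering plots).
#' @param seed Seed used only by `sign_rule = "random"`.
#' @return Object of class `chain2d`: a matrix of vertices (`n_angles + 2`
#'   rows, columns `x`, `y`).
#' @export
build_chain <- function(angles, sign_rule = c("positive", "alternating",
                                              "random"), seed = 1L) {
  angles <- .as_angles(angles)
  sign_rule <- match.arg(sign_rule)
  n <- length(angles)
  signs <- switch(sign_rule,
    positive = rep(1, n),
    alternating = rep_len(c(1, -1), n),
    random = {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      set.seed(seed)
      s <- sample(c(-1, 1), n, replace = TRUE)
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      s
    })
  headings <- cumsum(c(0, signs * angles * pi / 180))
  verts <- rbind(c(0, 0), cbind(cumsum(cos(headings)), cumsum(sin(headings))))
  colnames(verts) <- c("x", "y")
  structure(verts, class = c("chain2d", "matrix", "array"))
}

#' Plot a semantic chain diagram
#'
#' Draws the discrete chain with the start vertex in red and the end vertex
#' in green, the usual way these word-trajectory diagrams are shown.
#'
#' @param x A `chain2d` from [build_chain()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.chain2d <- function(x, ...) {
  v <- unclass(x)
  graphics::plot(v, type = "l", asp = 1, xlab = "", ylab = "", ...)
  graphics::points(v[1, 1], v[1, 2], col = "red", pch = 19, cex = 1.2)
  graphics::points(v[nrow(v), 1], v[nrow(v), 2], col = "darkgreen",
                   pch = 19, cex = 1.2)
  invisible(x)
}

#' Estimate the persistence length of an angle sequence
#'
#' Under the discrete worm-like-chain law, directional correlation decays as
#' `<cos theta(s)> = exp(-s / Lp)` with lag `s` in segments. Two estimators:
#'
#' * `adjacent_cosine` (default): `Lp = -1 / log(cbar)` where `cbar` is the
#'   mean cosine of the adjacent turning angles. `cbar <= 0` maps to
#'   `Lp = 0`; `cbar = 1` (a perfectly straight chain) is flagged infinite.
#' * `lag_decay_fit`: the lag-`s` correlation is taken as the mean over
#'   windows of the product of the window's adjacent cosines (the exact
#'   expectation `cbar^s` under independent symmetric bending); `log C(s)`
#'   is regressed through the origin on `s = 1..min(5, n-1)` and the slope
#'   is `-1/Lp`. Lags with non-positive `C(s)` are dropped.
#'
#' The decay law is applied to the turning angles as data, without the
#' thermal-fluctuation factor-of-two correction used for 2D polymers; see
#' the methods vignette.
#'
#' @param angles An `angle_sequence` or numeric vector of degrees; at least
#'   3 angles (i.e. 4 words) are required.
#' @param estimator `"adjacent_cosine"` or `"lag_decay_fit"`.
#' @return Object of class `persistence_estimate`: list with `lp_segments`
#'   (positive number, `Inf`, or `NA` on insufficient data), `estimator`,
#'   `n_angles`, `mean_cos` and `status`.
#' @export
estimate_persistence_length <- function(angles,
                                        estimator = c("adjacent_cosine",
                                                      "lag_decay_fit")) {
  estimator <- match.arg(estimator)
  angles <- .as_angles(angles)
  n <- length(angles)
  out <- function(lp, status = "ok", cbar = NA_real_) {
    structure(list(lp_segments = lp, estimator = estimator, n_angles = n,
                   mean_cos = cbar, status = status),
              class = "persistence_estimate")
  }
  if (n < 3L) return(out(NA_real_, "insufficient_data"))
  cosines <- cos(angles * pi / 180)
  cbar <- mean(cosines)
  if (estimator == "adjacent_cosine") {
    lp <- if (cbar <= 0) 0 else if (cbar >= 1) Inf else -1 / log(cbar)
    return(out(lp, cbar = cbar))
  }
  smax <- min(5L, n - 1L)
  corr <- vapply(seq_len(smax), function(s) {
    windows <- vapply(seq_len(n - s + 1L), function(i) {
      prod(cosines[i:(i + s - 1L)])
    }, numeric(1))
    mean(windows)
  }, numeric(1))
  keep <- corr > 0
  if (!any(keep)) return(out(0, cbar = cbar))
  s <- seq_len(smax)[keep]
  y <- log(corr[keep])
  slope <- sum(s * y) / sum(s^2)  # no-intercept fit: log C(0) = 0
  lp <- if (slope >= 0) Inf else -1 / slope
  out(lp, cbar = cbar)
}

#' @export
print.persistence_estimate <- function(x, ...) {
  cat(sprintf("<persistence_estimate> Lp = %s segments (%s, %d angles)\n",
              format(x$lp_segments, digits = 4), x$estimator, x$n_angles))
  invisible(x)
}

#' Semantic-relatedness index (SR)
#'
#' The per-participant semantic strategy score: the mean cosine of the
#' turning angles between consecutive word vectors, floored at 0, so
#' `SR = max(0, cbar) = exp(-1 / Lp)` under the worm-like-chain law with the
#' adjacent-cosine estimator. SR lies in [0, 1]: 1 for a sequence of
#' semantically identical words (straight chain), 0 when consecutive words
#' are orthogonal or opposed on average. At least four in-vocabulary words
#' are required, because one or two angles cannot support a curvature
#' estimate; shorter sequences return an `insufficient_data` result and are
#' excluded upstream.
#'
#' @inheritParams turning_angles
#' @param estimator Persistence-length estimator to attach, see
#'   [estimate_persistence_length()].
#' @return Object of class `semantic_index`: list with `sr` (number in
#'   [0, 1] or `NA`), `lp` (a `persistence_estimate`), `n_angles`,
#'   `oov_words` and `status`.
#' @export
semantic_relatedness <- function(words, emb,
                                 estimator = c("adjacent_cosine",
                                               "lag_decay_fit")) {
  estimator <- match.arg(estimator)
  ang <- turning_angles(words, emb)
  if (length(ang$words_used) < 4L) {
    return(structure(list(sr = NA_real_,
                          lp = estimate_persistence_length(numeric(0)),
                          n_angles = length(ang$angles_deg),
                          oov_words = ang$oov_words,
                          status = "insufficient_data"),
                     class = "semantic_index"))
  }
  lp <- estimate_persistence_length(ang, estimator)
  cbar <- mean(cos(ang$angles_deg * pi / 180))
  structure(list(sr = min(1, max(0, cbar)), lp = lp,
                 n_angles = length(ang$angles_deg),
                 oov_words = ang$oov_words, status = "ok"),
            class = "semantic_index")
}

#' @export
print.semantic_index <- function(x, ...) {
  cat(sprintf("<semantic_index> SR = %s (Lp = %s segments, %d angles, %d OOV)\n",
              format(x$sr, digits = 3),
              format(x$lp$lp_segments, digits = 3),
              x$n_angles, length(x$oov_words)))
  invisible(x)
}
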