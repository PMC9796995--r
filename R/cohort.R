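# Cohort-level statistics: strategy-index table construction, exclusion
# rules, descriptives, Pearson correlations, and stepwise multiple
# regression with collinearity diagnostics.

.measure_cols <- c("nocw", "mcs", "nos", "sr")
.demo_cols <- c("age", "education", "mmse")

#' Compute the per-participant strategy-index table
#'
#' Runs the phonological and semantic scorers on each session and assembles
#' the cohort table: one row per participant with NoCW (number of correct
#' words), MCS (mean cluster size), NoS (number of switches), SR (semantic
#' relatedness), the persistence-length estimate, bookkeeping counts, and
#' demographics.
#'
#' @param sessions List of [fluency_session()] objects.
#' @param pron A [load_pron_lexicon()] lexicon.
#' @param emb An [load_embeddings()] lexicon.
#' @param estimator Persistence-length estimator, see
#'   [estimate_persistence_length()].
#' @param fallback Grapheme fallback for out-of-lexicon words, see
#'   [pair_relation()].
#' @return Data frame with columns `participant_id`, `n_words` (total
#'   productions), `nocw`, `mcs`, `nos`, `sr`, `lp`, `n_angles`, `n_oov`,
#'   `age`, `education`, `mmse`. `sr` is `NA` when the semantic analysis
#'   had insufficient data.
#' @export
strategy_indices <- function(sessions, pron, emb,
                             estimator = "adjacent_cosine",
                             fallback = TRUE) {
  rows <- lapply(sessions, function(s) {
    ph <- score_phonological(s, pron, fallback = fallback)
    se <- semantic_relatedness(s$tokens$norm, emb, estimator = estimator)
    meta <- s$meta
    num_or_na <- function(x) if (is.null(x) || !length(x)) NA_real_ else as.numeric(x)
    data.frame(
      participant_id = s$participant_id,
      n_words = nrow(s$tokens),
      nocw = ph$nocw,
      mcs = ph$mcs,
      nos = ph$nos,
      sr = se$sr,
      lp = se$lp$lp_segments,
      n_angles = se$n_angles,
      n_oov = length(se$oov_words),
      age = num_or_na(meta$age),
      education = num_or_na(meta$education),
      mmse = num_or_na(meta$mmse),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Apply cohort exclusion rules
#'
#' Mirrors the screening used for fluency cohorts: first remove
#' participants who produced fewer than `min_words` total words (the
#' minimum for a usable semantic curvature estimate), then, on the retained
#' set, remove participants whose value on any screened measure exceeds the
#' retained-set mean by more than `sd_threshold` standard deviations
#' (one-sided, above the mean, by default). Records missing a screened
#' measure after the word-count filter are excluded as unusable. Outlier
#' statistics are computed once on the post-word-count set and all flagged
#' rows are removed in one pass.
#'
#' @param cohort Data frame from [strategy_indices()] (needs `n_words` plus
#'   the screened measures).
#' @param min_words Minimum total productions (default 4).
#' @param sd_threshold Outlier threshold in SD units (default 3).
#' @param measures Columns screened for outliers; default `c("mcs", "sr")`.
#' @param two_sided Also flag values below `mean - sd_threshold * SD`.
#' @return List with `retained` (data frame) and `log` (data frame with
#'   `participant_id`, `reason` in
#'   `{too_few_words, outlier, unusable_record}`, `measure`, `value`).
#' @export
apply_exclusions <- function(cohort, min_words = 4, sd_threshold = 3,
                             measures = c("mcs", "sr"), two_sided = FALSE) {
  log0 <- data.frame(participant_id = character(), reason = character(),
                     measure = character(), value = numeric(),
                     stringsAsFactors = FALSE)
  if (is.null(cohort) || nrow(cohort) == 0L) {
    return(list(retained = cohort, log = log0))
  }
  log_rows <- list()
  few <- cohort$n_words < min_words
  for (i in which(few)) {
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(participant_id = cohort$participant_id[i],
                 reason = "too_few_words", measure = "n_words",
                 value = cohort$n_words[i], stringsAsFactors = FALSE)
  }
  cohort <- cohort[!few, , drop = FALSE]

  measures <- intersect(measures, names(cohort))
  unusable <- rep(FALSE, nrow(cohort))
  for (m in measures) unusable <- unusable | is.na(cohort[[m]])
  for (i in which(unusable)) {
    bad <- measures[is.na(unlist(cohort[i, measures]))][1]
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(participant_id = cohort$participant_id[i],
                 reason = "unusable_record", measure = bad,
                 value = NA_real_, stringsAsFactors = FALSE)
  }
  cohort <- cohort[!unusable, , drop = FALSE]

  if (nrow(cohort) >= 2L) {
    drop <- rep(FALSE, nrow(cohort))
    for (m in measures) {
      x <- cohort[[m]]
      mu <- mean(x)
      sdev <- stats::sd(x)
      if (!is.finite(sdev) || sdev == 0) next
      hi <- x > mu + sd_threshold * sdev
      lo <- if (two_sided) x < mu - sd_threshold * sdev else rep(FALSE, length(x))
      for (i in which((hi | lo) & !drop)) {
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(participant_id = cohort$participant_id[i],
                     reason = "outlier", measure = m, value = x[i],
                     stringsAsFactors = FALSE)
      }
      drop <- drop | hi | lo
    }
    cohort <- cohort[!drop, , drop = FALSE]
  }
  rownames(cohort) <- NULL
  list(retained = cohort,
       log = if (length(log_rows)) {
         do.call(rbind, c(log_rows, list(make.row.names = FALSE)))
       } else log0)
}

#' Descriptive statistics table
#'
#' Mean, SD and range per measure, laid out one measure per row the way
#' fluency-cohort descriptives are reported. SD uses the n-1 (sample)
#' convention; a single-row cohort reports SD 0.
#'
#' @param cohort Data frame of strategy indices.
#' @param columns Numeric columns to summarise; defaults to the four
#'   strategy measures present.
#' @return Data frame with columns `measure`, `n`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
describe_cohort <- function(cohort, columns = NULL) {
  if (is.null(cohort) || nrow(cohort) == 0L) stop("empty cohort")
  if (is.null(columns)) {
    columns <- intersect(c(.measure_cols, .demo_cols), names(cohort))
  }
  rows <- lapply(columns, function(cn) {
    x <- cohort[[cn]]
    x <- x[!is.na(x)]
    data.frame(measure = cn, n = length(x),
               mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Pearson correlation matrix with significance stars
#'
#' Pairwise-complete Pearson correlations over the strategy measures and
#' demographics, with two-sided p-values from the t-transform on n-2
#' degrees of freedom and the conventional 0.05 / 0.01 / 0.001 stars. No
#' multiple-testing correction is applied. A zero-variance column yields
#' `NA` for its pairs.
#'
#' @param cohort Data frame of strategy indices.
#' @param columns Columns to correlate; defaults to
#'   `nocw, mcs, nos, sr, age, education, mmse` (those present).
#' @return Object of class `correlation_table`: list of matrices `r`, `p`,
#'   `n`, `stars`.
#' @export
pearson_matrix <- function(cohort, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(c(.measure_cols, .demo_cols), names(cohort))
  }
  k <- length(columns)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- cohort[[columns[i]]]
      y <- cohort[[columns[j]]]
      ok <- !is.na(x) & !is.na(y)
      nmat[i, j] <- sum(ok)
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- NA_real_
        next
      }
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      rv <- stats::cor(x[ok], y[ok])
      r[i, j] <- rv
      n <- sum(ok)
      tv <- rv * sqrt((n - 2) / max(1 - rv^2, .Machine$double.eps))
      p[i, j] <- 2 * stats::pt(-abs(tv), df = n - 2)
    }
  }
  stars <- matrix("", k, k, dimnames = list(columns, columns))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  structure(list(r = r, p = p, n = nmat, stars = stars),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, digits = 3, ...) {
  disp <- matrix(paste0(format(round(x$r, digits)), x$stars),
                 nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "."
  cat("Pearson correlations (*, **, ***: p < .05, .01, .001)\n")
  print(disp, quote = FALSE)
  invisible(x)
}

#' Stepwise multiple regression with collinearity diagnostics
#'
#' Forward selection with backward elimination on partial-F p-values, the
#' rule pinned to the conventional entry/removal defaults of mainstream
#' statistics packages (enter at p < 0.05, remove at p > 0.10). At each
#' forward step the candidate with the smallest entry p-value below
#' `p_enter` joins the model; after each entry, any included predictor whose
#' p-value exceeds `p_remove` is dropped (largest first). For a single
#' added/removed term the partial F equals the squared t, so t-test
#' p-values are used. Candidates perfectly collinear with the current model
#' never enter. If no candidate passes `p_enter`, an intercept-only model
#' with R-squared 0 is returned rather than an error.
#'
#' Tolerance for each retained predictor is `1 - R^2` of that predictor
#' regressed on the other retained predictors; VIF is its reciprocal
#' (exactly, so `VIF * tolerance = 1`). A sole predictor has tolerance 1.
#'
#' @param cohort Data frame.
#' @param outcome Name of the outcome column (default `"nocw"`).
#' @param candidates Candidate predictor columns; defaults to
#'   `mcs, nos, sr, age, education, mmse` (those present).
#' @param p_enter,p_remove Entry and removal thresholds.
#' @return Object of class `stepwise_fit`: list with `outcome`, `selected`,
#'   `coefficients` (data frame with estimate, std. error, t, p, tolerance,
#'   VIF), `r_squared`, `f_statistic` (`value`, `df1`, `df2`, `p`), `n`,
#'   `trace` (data frame of steps), and the final `model` (an `lm` or
#'   `NULL`).
#' @export
stepwise_regression <- function(cohort, outcome = "nocw",
                                candidates = NULL,
                                p_enter = 0.05, p_remove = 0.10) {
  if (is.null(candidates)) {
    candidates <- intersect(c("mcs", "nos", "sr", .demo_cols), names(cohort))
  }
  dat <- cohort[, c(outcome, candidates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n < 10L) stop("stepwise regression needs at least 10 complete rows, got ", n)

  selected <- character(0)
  trace <- list()
  term_p <- function(vars, term) {
    fml <- stats::reformulate(vars, response = outcome)
    fit <- stats::lm(fml, data = dat)
    cf <- summary(fit)$coefficients
    if (!term %in% rownames(cf)) return(NA_real_)  # aliased: perfect collinearity
    cf[term, "Pr(>|t|)"]
  }
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pv <- vapply(pool, function(v) term_p(c(selected, v), v), numeric(1))
      pv[is.na(pv)] <- 1
      if (min(pv) < p_enter) {
        add <- pool[which.min(pv)]
        selected <- c(selected, add)
        trace[[length(trace) + 1L]] <-
          data.frame(step = length(trace) + 1L, action = "enter",
                     term = add, p = min(pv),
                     r_squared = summary(stats::lm(
                       stats::reformulate(selected, outcome), dat))$r.squared,
                     stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    if (length(selected)) {
      pv <- vapply(selected, function(v) term_p(selected, v), numeric(1))
      pv[is.na(pv)] <- 1
      if (max(pv) > p_remove) {
        drop <- selected[which.max(pv)]
        selected <- setdiff(selected, drop)
        trace[[length(trace) + 1L]] <-
          data.frame(step = length(trace) + 1L, action = "remove",
                     term = drop, p = max(pv),
                     r_squared = if (length(selected)) {
                       summary(stats::lm(
                         stats::reformulate(selected, outcome), dat))$r.squared
                     } else 0,
                     stringsAsFactors = FALSE)
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  trace_df <- if (length(trace)) {
    do.call(rbind, c(trace, list(make.row.names = FALSE)))
  } else {
    data.frame(step = integer(), action = character(), term = character(),
               p = numeric(), r_squared = numeric(), stringsAsFactors = FALSE)
  }
  if (!length(selected)) {
    return(structure(list(outcome = outcome, selected = character(0),
                          coefficients = data.frame(),
                          r_squared = 0,
                          f_statistic = list(value = NA_real_, df1 = NA_integer_,
                                             df2 = NA_integer_, p = NA_real_),
                          n = n, trace = trace_df, model = NULL),
                     class = "stepwise_fit"))
  }
  fit <- stats::lm(stats::reformulate(selected, outcome), data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients[selected, , drop = FALSE]
  tol <- vapply(selected, function(v) {
    others <- setdiff(selected, v)
    if (!length(others)) return(1)
    r2 <- summary(stats::lm(stats::reformulate(others, v), data = dat))$r.squared
    1 - r2
  }, numeric(1))
  coef_df <- data.frame(term = selected,
                        estimate = cf[, "Estimate"],
                        std_error = cf[, "Std. Error"],
                        t = cf[, "t value"],
                        p = cf[, "Pr(>|t|)"],
                        tolerance = tol,
                        vif = 1 / tol,
                        stringsAsFactors = FALSE, row.names = NULL)
  fstat <- sm$fstatistic
  structure(list(outcome = outcome, selected = selected,
                 coefficients = coef_df,
                 r_squared = sm$r.squared,
                 f_statistic = list(value = unname(fstat[1]),
                                    df1 = unname(fstat[2]),
                                    df2 = unname(fstat[3]),
                                    p = unname(stats::pf(fstat[1], fstat[2],
                                                         fstat[3],
                                                         lower.tail = FALSE))),
                 n = n, trace = trace_df, model = fit),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("Stepwise regression: %s ~ %s (n = %d)\n", x$outcome,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "1", x$n))
  if (length(x$selected)) {
    print(x$coefficients, digits = 4)
    cat(sprintf("R^2 = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
                x$r_squared, x$f_statistic$df1, x$f_statistic$df2,
                x$f_statistic$value, x$f_statistic$p))
  } else {
    cat("No candidate passed the entry threshold; R^2 = 0\n")
  }
  invisible(x)
}
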