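# End-to-end pipeline driver and command-line interface.

#' Pipeline configuration
#'
#' Collects every input path and tunable for a cohort run. The
#' configuration is serialised verbatim (with a content hash) into the
#' output directory so any artifact can be traced to the exact settings
#' that produced it.
#'
#' @param transcripts_dir Directory of transcripts (`.cha` parsed as
#'   minimal CHAT, anything else as plain one-word-per-line lists).
#' @param lexicon Path to a CMU-format pronunciation lexicon.
#' @param embeddings Path to a word2vec/GloVe text embedding table.
#' @param out_dir Output directory.
#' @param demographics Optional demographics CSV.
#' @param target_letter Target letter of the trial.
#' @param min_words,sd_threshold Exclusion rules, see [apply_exclusions()].
#' @param p_enter,p_remove Stepwise thresholds, see
#'   [stepwise_regression()].
#' @param estimator Persistence-length estimator.
#' @param sign_rule Chain-plot sign rule, see [build_chain()].
#' @param fallback Grapheme fallback for out-of-lexicon words.
#' @param make_plots Write per-participant chain plots (PNG).
#' @param seed Seed recorded for provenance (the scoring pipeline itself is
#'   deterministic; the seed feeds plot sign randomisation).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(transcripts_dir, lexicon, embeddings, out_dir,
                            demographics = NULL, target_letter = "f",
                            min_words = 4, sd_threshold = 3,
                            p_enter = 0.05, p_remove = 0.10,
                            estimator = "adjacent_cosine",
                            sign_rule = "positive", fallback = TRUE,
                            make_plots = FALSE, seed = 1L) {
  structure(list(transcripts_dir = transcripts_dir, lexicon = lexicon,
                 embeddings = embeddings, out_dir = out_dir,
                 demographics = demographics, target_letter = target_letter,
                 min_words = min_words, sd_threshold = sd_threshold,
                 p_enter = p_enter, p_remove = p_remove,
                 estimator = estimator, sign_rule = sign_rule,
                 fallback = fallback, make_plots = make_plots,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Polynomial rolling hash over the serialised configuration; cheap,
# dependency-free provenance tag (stays within exact double-integer range).
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      null = "null"))
  h <- 5381
  for (b in bytes) {
    h <- (h * 131 + b) %% 1000000007
  }
  sprintf("%08x", h)
}

.write_empty <- function(path, cols) {
  df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                      cols))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full cohort pipeline
#'
#' Reads and scores every transcript, applies the exclusion rules, and
#' writes the cohort outputs: per-participant strategy indices, the
#' exclusion log, descriptive statistics, the Pearson correlation table
#' (with significance stars), the stepwise regression report
#' (JSON and text), and a manifest recording the configuration, its hash,
#' stage counts and file list. Per-participant failures are logged and the
#' run continues; missing input paths fail early by name. A cohort left
#' empty after exclusions still writes every file (headers only) and skips
#' the statistics.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the strategy-index and
#'   exclusion data are also returned as attributes `"indices"`,
#'   `"retained"`, `"exclusions"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("transcripts_dir", "lexicon", "embeddings")) {
    if (!file.exists(config[[p]])) {
      stop("missing input (", p, "): ", config[[p]])
    }
  }
  if (!is.null(config$demographics) && !file.exists(config$demographics)) {
    stop("missing input (demographics): ", config$demographics)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logf, append = TRUE)
  }
  log_line("config hash %s", hash)

  pron <- load_pron_lexicon(config$lexicon)
  emb <- load_embeddings(config$embeddings)
  files <- list.files(config$transcripts_dir, full.names = TRUE,
                      pattern = "\\.(cha|txt)$")
  log_line("%d transcripts, %d lexicon words, %d embedding words",
           length(files), length(pron), nrow(emb$vectors))

  sessions <- list()
  for (f in files) {
    s <- tryCatch({
      if (grepl("\\.cha$", f)) {
        read_chat_session(f, config$target_letter)
      } else {
        read_plain_list(f, config$target_letter)
      }
    }, error = function(e) {
      log_line("FAILED %s: %s", basename(f), conditionMessage(e))
      NULL
    })
    if (!is.null(s)) sessions[[length(sessions) + 1L]] <- s
  }
  if (!is.null(config$demographics)) {
    sessions <- attach_demographics(sessions,
                                    read_demographics(config$demographics))
  }
  log_line("%d sessions read", length(sessions))

  indices <- strategy_indices(sessions, pron, emb,
                              estimator = config$estimator,
                              fallback = config$fallback)
  excl <- apply_exclusions(indices, min_words = config$min_words,
                           sd_threshold = config$sd_threshold)
  retained <- excl$retained
  log_line("%d retained, %d excluded", nrow(retained), nrow(excl$log))

  paths <- list(indices = "indices.csv", exclusions = "exclusions.csv",
                descriptives = "descriptives.csv",
                correlations = "correlations.csv",
                correlations_p = "correlation_pvalues.csv",
                regression_json = "regression.json",
                regression_txt = "regression.txt")
  paths <- lapply(paths, function(p) file.path(config$out_dir, p))
  utils::write.csv(indices, paths$indices, row.names = FALSE)
  utils::write.csv(excl$log, paths$exclusions, row.names = FALSE)

  reg <- NULL
  if (nrow(retained) > 0L) {
    utils::write.csv(describe_cohort(retained), paths$descriptives,
                     row.names = FALSE)
    ct <- pearson_matrix(retained)
    disp <- matrix(paste0(format(round(ct$r, 3), trim = TRUE), ct$stars),
                   nrow(ct$r), dimnames = dimnames(ct$r))
    disp[is.na(ct$r)] <- ""
    utils::write.csv(disp, paths$correlations)
    utils::write.csv(round(ct$p, 6), paths$correlations_p)
    reg <- tryCatch(
      stepwise_regression(retained, p_enter = config$p_enter,
                          p_remove = config$p_remove),
      error = function(e) {
        log_line("regression skipped: %s", conditionMessage(e))
        NULL
      })
  } else {
    .write_empty(paths$descriptives, c("measure", "n", "mean", "sd", "min", "max"))
    utils::write.csv(data.frame(), paths$correlations)
    utils::write.csv(data.frame(), paths$correlations_p)
  }
  if (!is.null(reg)) {
    jsonlite::write_json(
      list(config_hash = hash, outcome = reg$outcome,
           selected = reg$selected, coefficients = reg$coefficients,
           r_squared = reg$r_squared, f_statistic = reg$f_statistic,
           n = reg$n, trace = reg$trace),
      paths$regression_json, auto_unbox = TRUE, digits = NA, null = "null")
    txt <- utils::capture.output(print(reg))
    writeLines(c(sprintf("# config %s", hash), txt), paths$regression_txt)
  } else {
    jsonlite::write_json(list(config_hash = hash, selected = character(0),
                              r_squared = 0),
                         paths$regression_json, auto_unbox = TRUE)
    writeLines(c(sprintf("# config %s", hash), "no regression computed"),
               paths$regression_txt)
  }

  if (isTRUE(config$make_plots) && length(sessions)) {
    pdir <- file.path(config$out_dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    for (s in sessions) {
      ang <- turning_angles(s$tokens$norm, emb)
      if (ang$status != "ok") next
      grDevices::png(file.path(pdir, paste0(s$participant_id, ".png")),
                     480, 480)
      plot(build_chain(ang, sign_rule = config$sign_rule,
                       seed = config$seed),
           main = s$participant_id)
      grDevices::dev.off()
    }
  }

  jsonlite::write_json(
    list(config = unclass(config), config_hash = hash,
         n_transcripts = length(files), n_sessions = length(sessions),
         n_retained = nrow(retained), n_excluded = nrow(excl$log),
         files = vapply(paths, basename, character(1))),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  log_line("done")

  out <- config$out_dir
  attr(out, "indices") <- indices
  attr(out, "retained") <- retained
  attr(out, "exclusions") <- excl$log
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `score` (one transcript), `cohort` (full pipeline),
#' `simulate` (write a synthetic cohort as pipeline inputs), `plot` (chain
#' diagram for one transcript). Invoked by the installed
#' `exec/letterfluency` script as
#' `Rscript exec/letterfluency <subcommand> [options]`.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   trailing arguments of the running script).
#' @return Exit status, invisibly (0 on success).
#' @export
lf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: letterfluency <score|cohort|simulate|plot> [options]"
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  opt_list <- switch(sub,
    score = list(
      optparse::make_option("--transcript", type = "character"),
      optparse::make_option("--lexicon", type = "character"),
      optparse::make_option("--embeddings", type = "character"),
      optparse::make_option("--letter", type = "character", default = "f")),
    cohort = list(
      optparse::make_option("--transcripts", type = "character"),
      optparse::make_option("--lexicon", type = "character"),
      optparse::make_option("--embeddings", type = "character"),
      optparse::make_option("--demographics", type = "character",
                            default = NULL),
      optparse::make_option("--out", type = "character"),
      optparse::make_option("--letter", type = "character", default = "f"),
      optparse::make_option("--min-words", type = "integer", default = 4L,
                            dest = "min_words"),
      optparse::make_option("--sd-threshold", type = "double", default = 3,
                            dest = "sd_threshold"),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--plots", action = "store_true",
                            default = FALSE)),
    simulate = list(
      optparse::make_option("--preset", type = "character", default = NULL),
      optparse::make_option("--n", type = "integer", default = 47L),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character")),
    plot = list(
      optparse::make_option("--transcript", type = "character"),
      optparse::make_option("--embeddings", type = "character"),
      optparse::make_option("--out", type = "character"),
      optparse::make_option("--sign-rule", type = "character",
                            default = "positive", dest = "sign_rule"),
      optparse::make_option("--seed", type = "integer", default = 1L)),
    {
      message(usage)
      return(invisible(1L))
    })
  opts <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                               args = rest)
  switch(sub,
    score = {
      sess <- read_any_transcript(opts$transcript, opts$letter)
      pron <- load_pron_lexicon(opts$lexicon)
      emb <- load_embeddings(opts$embeddings)
      ph <- score_phonological(sess, pron)
      se <- semantic_relatedness(sess$tokens$norm, emb)
      cat(jsonlite::toJSON(list(
        participant_id = sess$participant_id, n_words = nrow(sess$tokens),
        nocw = ph$nocw, mcs = ph$mcs, nos = ph$nos, sr = se$sr,
        lp_segments = se$lp$lp_segments, n_oov = length(se$oov_words)),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"), "\n")
    },
    cohort = {
      cfg <- pipeline_config(opts$transcripts, opts$lexicon, opts$embeddings,
                             opts$out, demographics = opts$demographics,
                             target_letter = opts$letter,
                             min_words = opts$min_words,
                             sd_threshold = opts$sd_threshold,
                             make_plots = opts$plots, seed = opts$seed)
      run_pipeline(cfg)
      message("wrote ", opts$out)
    },
    simulate = {
      cfg <- synth_config(n_participants = opts$n, seed = opts$seed,
                          preset = opts$preset)
      write_synthetic_inputs(simulate_cohort(cfg), opts$out)
      message("wrote ", opts$out)
    },
    plot = {
      sess <- read_any_transcript(opts$transcript, "f")
      emb <- load_embeddings(opts$embeddings)
      ang <- turning_angles(sess$tokens$norm, emb)
      if (ang$status != "ok") stop("insufficient in-vocabulary words to plot")
      grDevices::png(opts$out, 480, 480)
      plot(build_chain(ang, sign_rule = opts$sign_rule, seed = opts$seed),
           main = sess$participant_id)
      grDevices::dev.off()
      message("wrote ", opts$out)
    })
  invisible(0L)
}

#' Read a transcript of either supported format
#'
#' Dispatches on extension: `.cha` as minimal CHAT, otherwise a plain
#' one-word-per-line list.
#'
#' @inheritParams read_plain_list
#' @export
read_any_transcript <- function(path, target_letter = "f") {
  if (grepl("\\.cha$", path)) {
    read_chat_session(path, target_letter)
  } else {
    read_plain_list(path, target_letter)
  }
}
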