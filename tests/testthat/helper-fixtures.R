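# Shared fixtures and independent oracles.

lf_extdata <- function(name) {
  system.file("extdata", name, package = "letterfluency", mustWork = TRUE)
}

demo_pron <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- load_pron_lexicon(lf_extdata("cmudict-subset.txt"))
    lex
  }
})

demo_emb <- local({
  emb <- NULL
  function() {
    if (is.null(emb)) {
      emb <<- load_embeddings(lf_extdata("embeddings-demo-synthetic.txt"))
    }
    emb
  }
})

# Write a tiny word2vec-text embedding file from a named list of vectors.
write_emb_file <- function(vectors, header = FALSE) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  lines <- vapply(names(vectors), function(w) {
    paste(w, paste(vectors[[w]], collapse = " "))
  }, character(1))
  if (header) {
    lines <- c(paste(length(vectors), length(vectors[[1]])), lines)
  }
  writeLines(lines, path)
  path
}

write_lines_file <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent clustering oracle: test every adjacent pair on its own, then
# group maximal related runs with rle(). Shares only the pair relation with
# the implementation under test, as specified.
oracle_clusters <- function(tokens, lex) {
  n <- length(tokens)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer(), size = integer()))
  }
  if (n == 1L) return(data.frame(start = 1L, end = 1L, size = 0L))
  linked <- vapply(seq_len(n - 1L), function(i) {
    pair_relation(tokens[i], tokens[i + 1L], lex) != "none"
  }, logical(1))
  # group tokens: token i+1 joins token i's group iff linked[i]
  grp <- cumsum(c(TRUE, !linked))
  runs <- rle(grp)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  data.frame(start = as.integer(starts), end = as.integer(ends),
             size = as.integer(ends - starts))
}

# f-words from the demo lexicon, for random sequence generation.
demo_f_words <- function() {
  w <- names(demo_pron())
  w[startsWith(w, "f")]
}
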