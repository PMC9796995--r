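test_that("embedding files parse with and without a header", {
  v <- list(fa = c(1, 0), fb = c(0, 1), fc = c(1, 1))
  emb <- load_embeddings(write_emb_file(v))
  expect_identical(nrow(emb$vectors), 3L)
  expect_identical(emb$dim, 2L)
  emb2 <- load_embeddings(write_emb_file(v, header = TRUE))
  expect_identical(emb2$vectors, emb$vectors)

  bad <- write_lines_file(c("fa 1 0", "fb 1"))
  expect_error(load_embeddings(bad), "inconsistent")
  expect_warning(z <- load_embeddings(write_emb_file(list(fa = c(1, 0),
                                                          fz = c(0, 0)))),
                 "zero vector")
  expect_identical(rownames(z$vectors), "fa")
  expect_warning(d <- load_embeddings(write_lines_file(c("fa 1 0", "fa 0 1"))),
                 "duplicate")
  expect_identical(unname(d$vectors["fa", ]), c(1, 0))
})

test_that("turning angles are the arccos of consecutive cosines", {
  emb <- load_embeddings(write_emb_file(list(
    fa = c(1, 0), fb = c(0, 1), fc = c(-2, 0), fd = c(300, 0))))
  a <- turning_angles(c("fa", "fa", "fa"), emb)
  expect_equal(a$angles_deg, c(0, 0))
  expect_equal(turning_angles(c("fa", "fb"), emb)$angles_deg, 90)
  expect_equal(turning_angles(c("fa", "fc"), emb)$angles_deg, 180)
  # scale-free: fd is fa rescaled
  expect_equal(turning_angles(c("fd", "fb"), emb)$angles_deg, 90)

  oov <- turning_angles(c("fa", "zzz", "fb"), emb)
  expect_identical(oov$oov_words, "zzz")
  expect_equal(oov$angles_deg, 90)  # oov dropped, not zero-vectored

  short <- turning_angles(c("fa", "zzz"), emb)
  expect_identical(short$status, "insufficient_data")
  expect_length(short$angles_deg, 0L)
})

test_that("chain geometry follows the sign rule and angle magnitudes", {
  straight <- build_chain(c(0, 0))
  expect_equal(unclass(straight),
               cbind(x = 0:3, y = rep(0, 4)), ignore_attr = TRUE)
  expect_identical(nrow(build_chain(c(10, 20, 30))), 5L)  # n_angles + 2

  turn <- build_chain(90)
  expect_equal(unclass(turn), cbind(x = c(0, 1, 1), y = c(0, 0, 1)),
               ignore_attr = TRUE, tolerance = 1e-12)

  ee <- function(ch) sqrt(sum((ch[nrow(ch), ] - ch[1, ])^2))
  zig <- build_chain(rep(90, 4), sign_rule = "alternating")
  square <- build_chain(rep(90, 4), sign_rule = "positive")
  expect_gt(ee(zig), ee(square))
  # straightness limit: end-to-end distance equals the number of segments
  expect_equal(ee(build_chain(rep(0, 7))), 8)
  # reconstructed turning-angle magnitudes equal the inputs
  ang <- c(35, 120, 5)
  ch <- build_chain(ang, sign_rule = "random", seed = 99)
  seg <- diff(unclass(ch))
  got <- vapply(seq_len(nrow(seg) - 1L), function(i) {
    a <- seg[i, ]; b <- seg[i + 1, ]
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  }, numeric(1))
  expect_equal(got, ang, tolerance = 1e-8)
})

test_that("persistence length inverts the decay law", {
  inf_est <- estimate_persistence_length(rep(0, 5))
  expect_identical(inf_est$lp_segments, Inf)

  a <- acos(exp(-1)) * 180 / pi  # constant angle with cosine e^-1
  expect_equal(estimate_persistence_length(rep(a, 6))$lp_segments, 1.0)

  expect_identical(estimate_persistence_length(c(10, 20))$status,
                   "insufficient_data")
  expect_identical(estimate_persistence_length(rep(120, 5))$lp_segments, 0)

  lag <- estimate_persistence_length(rep(a, 10), estimator = "lag_decay_fit")
  expect_equal(lag$lp_segments, 1.0, tolerance = 1e-9)
  expect_identical(lag$estimator, "lag_decay_fit")
})

test_that("the two estimators agree on simulated worm-like chains", {
  set.seed(101)
  for (lp in c(2, 10)) {
    est <- vapply(1:120, function(i) {
      ang <- simulate_wlc_angles(lp, 50)
      c(estimate_persistence_length(ang)$lp_segments,
        estimate_persistence_length(ang, "lag_decay_fit")$lp_segments)
    }, numeric(2))
    m1 <- stats::median(est[1, ])
    m2 <- stats::median(est[2, ])
    expect_lt(abs(m1 - m2) / m1, 0.15)
    expect_lt(abs(m1 - lp) / lp, 0.15)
  }
})

test_that("semantic relatedness is bounded, monotone and lp-consistent", {
  emb <- load_embeddings(write_emb_file(list(
    fa = c(1, 0), fb = c(0, 1), fc = c(-1, 0), fd = c(0, -1))))
  expect_equal(semantic_relatedness(rep("fa", 4), emb)$sr, 1)
  expect_equal(semantic_relatedness(c("fa", "fb", "fc", "fd"), emb)$sr, 0)

  srs <- vapply(c(20, 40, 60, 80), function(deg) {
    rad <- deg * pi / 180
    v <- lapply(0:4, function(k) c(cos(k * rad), sin(k * rad)))
    names(v) <- paste0("fw", 0:4)
    semantic_relatedness(paste0("fw", 0:4),
                         load_embeddings(write_emb_file(v)))$sr
  }, numeric(1))
  expect_equal(srs, cos(c(20, 40, 60, 80) * pi / 180), tolerance = 1e-9)
  expect_true(all(diff(srs) < 0))

  si <- semantic_relatedness(c("fa", "fb", "fa", "fb", "fa"), emb)
  expect_equal(si$sr, exp(-1 / si$lp$lp_segments), tolerance = 1e-12)

  few <- semantic_relatedness(c("fa", "fb", "fa"), emb)
  expect_identical(few$status, "insufficient_data")
  expect_true(is.na(few$sr))
})
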