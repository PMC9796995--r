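# Helpers building small cohort tables directly.
mk_cohort <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("p%02d", seq_len(n)),
    n_words = pmax(4L, rpois(n, 8)),
    nocw = rpois(n, 7),
    mcs = runif(n, 0, 0.6),
    nos = rpois(n, 7),
    sr = runif(n, 0.4, 0.8),
    age = rnorm(n, 72, 8),
    education = rnorm(n, 12, 3),
    mmse = round(runif(n, 10, 28)),
    stringsAsFactors = FALSE
  )
}

test_that("exclusion rules remove short and outlying records in order", {
  co <- mk_cohort(20)
  co$n_words[1] <- 3L                       # below the 4-word minimum
  mu <- mean(co$sr[-1]); s <- sd(co$sr[-1])
  co$sr[2] <- mu + 5 * s                    # planted one-sided outlier
  res <- apply_exclusions(co)
  expect_identical(nrow(res$retained), 18L)
  expect_identical(sort(res$log$reason), c("outlier", "too_few_words"))
  expect_identical(res$log$participant_id[res$log$reason == "outlier"], "p02")
  expect_identical(res$log$measure[res$log$reason == "outlier"], "sr")

  # the screen is one-sided by default, two-sided on request
  co2 <- mk_cohort(20, seed = 2)
  co2$sr[3] <- mean(co2$sr[-3]) - 5 * sd(co2$sr[-3])
  expect_identical(nrow(apply_exclusions(co2)$retained), 20L)
  expect_identical(nrow(apply_exclusions(co2, two_sided = TRUE)$retained), 19L)
})

test_that("exclusions are idempotent on clean fixtures and log NA measures", {
  co <- mk_cohort(15, seed = 3)
  once <- apply_exclusions(co)
  twice <- apply_exclusions(once$retained)
  expect_identical(twice$retained, once$retained)
  expect_identical(nrow(twice$log), 0L)

  co$sr[5] <- NA
  res <- apply_exclusions(co)
  expect_identical(res$log$reason, "unusable_record")
  expect_identical(res$log$participant_id, "p05")

  empty <- apply_exclusions(co[0, ])
  expect_identical(nrow(empty$retained), 0L)
  expect_identical(nrow(empty$log), 0L)
})

test_that("descriptives use the stated conventions", {
  one <- data.frame(nocw = 7, mcs = 0.2, nos = 5, sr = 0.5)
  d1 <- describe_cohort(one)
  expect_equal(d1$sd, rep(0, 4))
  expect_equal(d1$mean[d1$measure == "nocw"], 7)

  two <- data.frame(nocw = c(2, 4))
  d2 <- describe_cohort(two, columns = "nocw")
  expect_equal(d2[, c("mean", "sd", "min", "max")],
               data.frame(mean = 3, sd = sd(c(2, 4)), min = 2, max = 4))

  co <- mk_cohort(47)
  d <- describe_cohort(co, columns = c("nocw", "mcs", "nos", "sr"))
  expect_identical(d$measure, c("nocw", "mcs", "nos", "sr"))
  expect_identical(d$n, rep(47L, 4))
  expect_error(describe_cohort(co[0, ]), "empty")
})

test_that("Pearson matrix matches hand and cor.test oracles", {
  co <- data.frame(nocw = c(1, 2, 3), nos = c(2, 4, 6), sr = c(6, 4, 5))
  ct <- pearson_matrix(co, columns = c("nocw", "nos", "sr"))
  expect_equal(ct$r["nocw", "nos"], 1)
  expect_equal(ct$r["nocw", "sr"], -0.5)    # hand computation
  expect_identical(diag(ct$r), c(nocw = 1, nos = 1, sr = 1))
  expect_equal(ct$r, t(ct$r))

  co2 <- mk_cohort(30, seed = 4)
  ct2 <- pearson_matrix(co2)
  ref <- cor.test(co2$nocw, co2$sr)
  expect_equal(ct2$r["nocw", "sr"], unname(ref$estimate))
  expect_equal(ct2$p["nocw", "sr"], ref$p.value)
  expect_true(all(abs(ct2$r) <= 1, na.rm = TRUE))

  co2$flat <- 5
  ct3 <- pearson_matrix(co2, columns = c("nocw", "flat"))
  expect_true(is.na(ct3$r["nocw", "flat"]))

  stars <- pearson_matrix(data.frame(a = 1:20,
                                     b = 1:20 + rnorm(20, 0, 0.1)),
                          columns = c("a", "b"))$stars
  expect_identical(stars["a", "b"], "***")
})

test_that("pairwise-complete handling uses each pair's available rows", {
  co <- mk_cohort(25, seed = 5)
  co$mmse[1:10] <- NA
  ct <- pearson_matrix(co)
  expect_identical(ct$n["nocw", "mmse"], 15)
  expect_identical(ct$n["nocw", "sr"], 25)
  ref <- cor.test(co$nocw[-(1:10)], co$mmse[-(1:10)])
  expect_equal(ct$r["nocw", "mmse"], unname(ref$estimate))
})

test_that("stepwise regression recovers a planted single predictor", {
  set.seed(6)
  n <- 200
  co <- data.frame(nos = rnorm(n), mcs = rnorm(n), sr = rnorm(n),
                   age = rnorm(n))
  co$nocw <- 0.9 * co$nos + rnorm(n, 0, 0.3)
  fit <- stepwise_regression(co, outcome = "nocw",
                             candidates = c("nos", "mcs", "sr", "age"))
  expect_identical(fit$selected, "nos")
  expect_equal(fit$coefficients$estimate, 0.9, tolerance = 0.1)
  expect_equal(fit$coefficients$tolerance, 1)
  expect_true(all(abs(fit$coefficients$vif * fit$coefficients$tolerance - 1)
                  < 1e-9))
  expect_true(all(diff(fit$trace$r_squared[fit$trace$action == "enter"]) >= 0))
})

test_that("stepwise handles collinearity, perfect fits and null models", {
  set.seed(7)
  n <- 60
  co <- data.frame(x1 = rnorm(n))
  co$x2 <- co$x1                            # perfect duplicate
  co$y <- 2 * co$x1 + rnorm(n, 0, 0.5)
  fit <- stepwise_regression(co, outcome = "y", candidates = c("x1", "x2"))
  expect_identical(fit$selected, "x1")
  expect_equal(fit$coefficients$tolerance, 1)

  co$y2 <- 3 * co$x1                        # exact linearity
  fit2 <- suppressWarnings(                  # lm warns on a perfect fit
    stepwise_regression(co, outcome = "y2", candidates = "x1"))
  expect_equal(fit2$r_squared, 1)

  co$noise <- rnorm(n)
  co$y3 <- rnorm(n)
  fit3 <- stepwise_regression(co, outcome = "y3", candidates = "noise")
  expect_identical(fit3$selected, character(0))
  expect_identical(fit3$r_squared, 0)

  expect_error(stepwise_regression(co[1:5, ], outcome = "y",
                                   candidates = "x1"), "at least 10")
})

test_that("multi-predictor fits report coherent diagnostics and F", {
  set.seed(8)
  n <- 120
  co <- data.frame(nos = rnorm(n), sr = rnorm(n))
  co$sr <- co$sr + 0.5 * co$nos            # induce collinearity
  co$nocw <- 0.8 * co$nos - 0.6 * co$sr + rnorm(n, 0, 0.4)
  fit <- stepwise_regression(co, outcome = "nocw", candidates = c("nos", "sr"))
  expect_setequal(fit$selected, c("nos", "sr"))
  expect_true(all(fit$coefficients$tolerance < 1))
  expect_true(all(abs(fit$coefficients$vif * fit$coefficients$tolerance - 1)
                  < 1e-9))
  # oracle: compare against lm on the same model
  ref <- lm(nocw ~ nos + sr, data = co)
  expect_equal(sort(fit$coefficients$estimate),
               sort(unname(coef(ref)[-1])), tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(ref)$r.squared)
  expect_equal(fit$f_statistic$value, unname(summary(ref)$fstatistic[1]))
})
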