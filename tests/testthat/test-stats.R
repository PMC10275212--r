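test_that("composite scores are component means, symmetric and missing-aware", {
  tab <- data.frame(fluency = c(0, 1.2, NA), stroop = c(0, -0.6, 0.5),
                    shift = c(0, 0.0, 1))
  out <- suppressWarnings(
    composite_score(tab, c("fluency", "stroop", "shift"), "EF"))
  expect_equal(out$EF[1], 0)
  expect_equal(out$EF[2], 0.2, tolerance = 1e-12)
  expect_true(is.na(out$EF[3]))
  expect_warning(composite_score(tab, c("fluency", "stroop", "shift"), "EF"),
                 "missing")
  # permutation invariance of components
  out2 <- suppressWarnings(
    composite_score(tab, c("shift", "fluency", "stroop"), "EF2"))
  expect_equal(out$EF, out2$EF2)
  expect_error(composite_score(tab, c("fluency", "nope"), "EF"), "nope")
})

test_that("collinearity reports VIF = 1 for orthogonal predictors and flags duplicates", {
  n <- 40
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)
  cl <- collinearity(data.frame(x1 = x1, x2 = x2))
  expect_equal(cl$vif, c(1, 1), tolerance = 1e-10)
  expect_equal(cl$tolerance, c(1, 1), tolerance = 1e-10)
  expect_false(any(cl$flagged))
  set.seed(1)
  z <- rnorm(n)
  cl2 <- suppressWarnings(collinearity(data.frame(a = z, b = z, c = rnorm(n))))
  expect_true(cl2$singular[1] && cl2$singular[2])
  expect_equal(cl2$tolerance[1], 0)
  expect_equal(cl2$vif[1], Inf)
  # the flag threshold is a tolerance of 0.2
  set.seed(2)
  u <- rnorm(200)
  v <- u + rnorm(200, sd = 0.3)  # tolerance well below 0.2
  cl3 <- collinearity(data.frame(u = u, v = v, w = rnorm(200)))
  expect_true(cl3$flagged[1])
  expect_false(cl3$flagged[3])
  expect_equal(cl3$tolerance, 1 / cl3$vif, tolerance = 1e-12)
})

test_that("backward elimination removes noise predictors and keeps an exact fit", {
  set.seed(10)
  n <- 30
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  d <- data.frame(y = 2 * x1, x1 = x1, x2 = x2)
  fit <- suppressWarnings(stepwise_blockwise(d, "y", block1 = c("x1", "x2")))
  final <- fit$models[[length(fit$models)]]
  expect_identical(final$predictors, "x1")
  expect_equal(final$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$removal_history[[1]]$predictor, "x2")
  # model sequence has strictly decreasing predictor counts
  counts <- vapply(fit$models, function(m) length(m$predictors), integer(1))
  expect_true(all(diff(counts) < 0))
})

test_that("a single-predictor model reproduces closed-form simple regression", {
  set.seed(11)
  n <- 25
  x <- rnorm(n)
  y <- 1.5 * x + rnorm(n, sd = 0.5)
  d <- data.frame(y = y, x = x)
  fit <- stepwise_blockwise(d, "y", block1 = "x", p_remove = 1)
  final <- fit$models[[1]]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(final$coefficients[["x"]], slope, tolerance = 1e-10)
  expect_equal(final$coefficients[["(Intercept)"]],
               mean(y) - slope * mean(x), tolerance = 1e-10)
  # standardized beta of a single predictor equals the Pearson correlation
  expect_equal(unname(final$std_beta["x"]), cor(x, y), tolerance = 1e-10)
})

test_that("degrees of freedom are bookkept as (k, n - k - 1)", {
  set.seed(12)
  n <- 33
  x <- rnorm(n)
  noise <- rnorm(n)
  d <- data.frame(y = x + rnorm(n, sd = 0.4), x = x, z = noise)
  fit <- stepwise_blockwise(d, "y", block1 = c("x", "z"))
  final <- fit$models[[length(fit$models)]]
  expect_identical(final$predictors, "x")
  expect_equal(final$df, c(1, 31))
})

test_that("forced block-2 predictors survive elimination and forward selection agrees", {
  set.seed(13)
  n <- 40
  x <- rnorm(n)
  m <- rnorm(n)
  junk1 <- rnorm(n); junk2 <- rnorm(n)
  d <- data.frame(y = x + 0.8 * m + rnorm(n, sd = 0.3),
                  x = x, junk1 = junk1, junk2 = junk2, m = m)
  bw <- stepwise_blockwise(d, "y", block1 = c("x", "junk1", "junk2"),
                           block2 = "m")
  finals <- lapply(bw$models, `[[`, "predictors")
  expect_true(all(vapply(finals, function(p) "m" %in% p, logical(1))))
  fw <- stepwise_blockwise(d, "y", block1 = c("x", "junk1", "junk2"),
                           block2 = "m", direction = "forward")
  expect_setequal(fw$models[[length(fw$models)]]$predictors, c("x", "m"))
  expect_setequal(bw$models[[length(bw$models)]]$predictors, c("x", "m"))
  # both agree with exhaustive best subset on the dominant-predictor design
  subsets <- unlist(lapply(0:3, function(k)
    combn(c("x", "junk1", "junk2"), k, simplify = FALSE)), recursive = FALSE)
  adj <- vapply(subsets, function(s) {
    f <- reformulate(c(s, "m"), response = "y")
    summary(lm(f, d))$adj.r.squared
  }, numeric(1))
  best <- subsets[[which.max(adj)]]
  expect_setequal(c(best, "m"),
                  bw$models[[length(bw$models)]]$predictors)
})

test_that("block 2 can enter after block-1 selection", {
  set.seed(14)
  n <- 40
  d <- data.frame(y = rnorm(n), x = rnorm(n), m = rnorm(n))
  fit <- stepwise_blockwise(d, "y", block1 = "x", block2 = "m",
                            block2_entry = "after")
  last <- fit$models[[length(fit$models)]]
  expect_true("m" %in% last$predictors)
  expect_identical(last$note, "block 2 entered")
})

test_that("stepwise rejects degenerate designs", {
  d <- data.frame(y = rnorm(10), x = rnorm(10))
  expect_error(stepwise_blockwise(d, "y", block1 = character(0)), "empty")
  d2 <- data.frame(y = rnorm(10), x = rnorm(10))
  d2$x2 <- d2$x
  suppressWarnings(
    expect_error(stepwise_blockwise(d2, "y", block1 = c("x", "x2"),
                                    p_remove = 1e-9),
                 "rank-deficient"))
})

test_that("R2 and adjusted R2 match their independent definitions", {
  set.seed(15)
  n <- 28
  d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n))
  fit <- stepwise_blockwise(d, "y", block1 = c("a", "b"), p_remove = 1)
  m <- fit$models[[1]]
  sse <- sum((m$observed - m$fitted)^2)
  sst <- sum((m$observed - mean(m$observed))^2)
  k <- length(m$predictors)
  expect_equal(m$r_squared, 1 - sse / sst, tolerance = 1e-12)
  expect_equal(m$adj_r_squared,
               1 - (1 - m$r_squared) * (n - 1) / (n - k - 1),
               tolerance = 1e-12)
  expect_lte(m$adj_r_squared, m$r_squared)
})

test_that("the hierarchical quadratic model detects a pure quadratic exactly", {
  age <- seq(20, 70, length.out = 33)
  y <- (age - 45)^2
  hq <- suppressWarnings(hierarchical_quadratic(age, y))
  expect_equal(hq$model2$r_squared, 1, tolerance = 1e-9)
  expect_lt(hq$p_change, 1e-12)
  expect_equal(hq$model2$df, c(2, 30))
  expect_error(hierarchical_quadratic(rep(50, 10), rnorm(10)), "constant")
})

test_that("the quadratic F-change test has nominal type-I error", {
  set.seed(16)
  reps <- 1000
  hits <- vapply(seq_len(reps), function(k) {
    age <- runif(33, 20, 70)
    y <- rnorm(33)
    hierarchical_quadratic(age, y)$p_change < 0.05
  }, logical(1))
  rate <- mean(hits)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("LOOCV R2 is 100 under perfect prediction and matches a fold-loop oracle", {
  x <- seq(1, 12)
  y <- 3 * x + 2
  expect_equal(loocv_r2(data.frame(x = x), y), 100, tolerance = 1e-9)
  set.seed(17)
  X <- data.frame(a = rnorm(12), b = rnorm(12))
  yy <- 0.5 * X$a + rnorm(12)
  got <- loocv_r2(X, yy)
  yhat <- vapply(1:12, function(i) {
    fit <- lm(yy[-i] ~ a + b, data = X[-i, ])
    sum(c(1, X$a[i], X$b[i]) * coef(fit))
  }, numeric(1))
  want <- 100 * (1 - sum((yy - yhat)^2) / sum(yy^2))
  expect_equal(got, want, tolerance = 1e-10)
  # the denominator is uncentered: all-zero predictions give exactly 0
  expect_equal(100 * (1 - sum((yy - 0)^2) / sum(yy^2)), 0)
})
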