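make_series <- function(mat, fs) epoched_series(mat, fs)

test_that("bandpass preserves in-band tones and annihilates out-of-band tones", {
  fs <- 128
  S <- 512
  t <- (0:(S - 1)) / fs
  tone <- function(f) sin(2 * pi * f * t)
  theta <- band_spec("theta")
  # 6 Hz is bin-aligned (6 * 512 / 128 = 24) and inside theta 4-8 Hz
  s_in <- make_series(cbind(tone(6)), fs)
  out_in <- bandpass(s_in, theta)
  expect_gte(sum(out_in$values^2) / sum(s_in$values^2), 0.999)
  # 20 Hz is bin-aligned and outside theta
  s_out <- make_series(cbind(tone(20)), fs)
  out_out <- bandpass(s_out, theta)
  expect_lte(sum(out_out$values^2), 1e-6 * sum(s_out$values^2))
})

test_that("bandpass satisfies the Parseval identity on white noise", {
  set.seed(42)
  fs <- 128
  S <- 256
  x <- rnorm(S)
  band <- band_spec("beta")
  out <- bandpass(make_series(cbind(x), fs), band)$values[1, , 1]
  X <- fft(x)
  f <- (0:(S - 1)) * fs / S
  f <- pmin(f, fs - f)
  keep <- f >= band$f_lo & f < band$f_hi
  expect_equal(sum(out^2), sum(Mod(X[keep])^2) / S, tolerance = 1e-10)
})

test_that("bandpass rejects bands at or above Nyquist", {
  s <- make_series(cbind(rnorm(64)), 64)
  expect_error(bandpass(s, band_spec("gamma")), "gamma")
})

test_that("the canonical band table is consistent", {
  tab <- canonical_bands()
  expect_identical(tab$name, c("delta", "theta", "lower_alpha",
                               "upper_alpha", "beta", "gamma"))
  expect_true(all(tab$f_lo < tab$f_hi))
  # adjacent bands tile the spectrum: each upper edge is the next lower edge
  expect_equal(tab$f_hi[-6], tab$f_lo[-1])
  expect_error(band_spec("mu"), "unknown")
})

test_that("pli_pair matches its analytic 0 and 1 cases", {
  t <- (0:511) / 128
  x <- sin(2 * pi * 10 * t)
  expect_equal(pli_pair(x, x), 0)
  # quarter-cycle delay of a pure sinusoid: constant-sign phase difference
  y <- sin(2 * pi * 10 * t - pi / 2)
  expect_equal(pli_pair(x, y), 1)
  expect_error(pli_pair(x, rep(1, length(x))), "constant")
})

test_that("pli_pair equals the brute-force sign-of-phase-difference oracle", {
  set.seed(7)
  for (k in 1:5) {
    n <- 256
    common <- cumsum(rnorm(n, sd = 0.2)) + 2 * pi * 11 * (1:n) / 128
    x <- sin(common) + rnorm(n, sd = 0.3)
    y <- sin(common + 0.9) + rnorm(n, sd = 0.3)
    expect_equal(pli_pair(x, y), oracle_pli(x, y), tolerance = 1e-12)
  }
})

test_that("PLI is invariant to per-channel amplitude rescaling", {
  set.seed(8)
  sub <- test_subject(n_regions = 10, n_epochs = 2, epoch_len = 256)
  series <- generate_band_series(sub, "beta", seed = 5)
  scaled <- series
  scaled$values[, , 3] <- 5 * scaled$values[, , 3]
  band <- band_spec("beta")
  expect_equal(pli_matrix(series, band)$weights,
               pli_matrix(scaled, band)$weights, tolerance = 1e-12)
})

test_that("pli_matrix equals the mean of per-epoch brute-force PLI matrices", {
  set.seed(21)
  fs <- 128
  S <- 256
  vals <- array(rnorm(2 * S * 3), dim = c(2, S, 3))
  series <- epoched_series(vals, fs)
  band <- band_spec("beta")
  got <- pli_matrix(series, band)$weights
  filt <- bandpass(series, band)
  want <- matrix(0, 3, 3)
  for (e in 1:2) {
    for (i in 1:2) for (j in (i + 1):3) {
      p <- oracle_pli(filt$values[e, , i], filt$values[e, , j])
      want[i, j] <- want[i, j] + p / 2
    }
  }
  want <- want + t(want)
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("pli_matrix returns zero off-diagonals for copies of one signal and stays in [0,1]", {
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.7), 300))
  vals <- array(rep(x, 4), dim = c(1, 300, 4))
  series <- epoched_series(vals, 128)
  W <- pli_matrix(series, band_spec("beta"))$weights
  expect_true(all(W == 0))
  vals2 <- array(rnorm(2 * 256 * 4), dim = c(2, 256, 4))
  W2 <- pli_matrix(epoched_series(vals2, 128), band_spec("theta"))$weights
  expect_true(all(W2 >= 0 & W2 <= 1))
  expect_true(all(diag(W2) == 0))
  expect_equal(W2, t(W2))
})

test_that("white-noise PLI shrinks as epochs x samples grows", {
  # independent channels: the PLI floor scales like 1/sqrt(samples); compare
  # the study-scale epoch grid (88 x 4096) with a small grid (8 x 512)
  mean_offdiag <- function(E, S, seed) {
    set.seed(seed)
    vals <- array(rnorm(E * S * 3), dim = c(E, S, 3))
    W <- pli_matrix(epoched_series(vals, 1250), band_spec("beta"))$weights
    mean(W[upper.tri(W)])
  }
  big <- vapply(1:10, function(s) mean_offdiag(88, 4096, s), numeric(1))
  small <- vapply(1:10, function(s) mean_offdiag(8, 512, s + 100), numeric(1))
  expect_lt(mean(big), mean(small))
  # filtered white noise carries ~2*bw*T independent sign samples per epoch;
  # for beta (17 Hz) at 3.28 s epochs the floor is sqrt(2/(pi*111)) ~ 0.076
  expect_lt(mean(big), 0.12)
})

test_that("correlation_matrix matches the textbook formula and its affine cases", {
  set.seed(5)
  x <- rnorm(50)
  m <- cbind(a = x, b = -x + rnorm(50, sd = 1e-12), c = 2 * x + 3)
  W <- correlation_matrix(m)$weights
  expect_equal(W[1, 2], 1, tolerance = 1e-6)
  expect_equal(W[1, 3], 1, tolerance = 1e-12)
  # closed-form Pearson r on a seeded 5-region sample
  X <- matrix(rnorm(40 * 5), 40, 5)
  W2 <- correlation_matrix(X)$weights
  for (i in 1:4) for (j in (i + 1):5) {
    xi <- X[, i]; xj <- X[, j]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(W2[i, j], abs(r), tolerance = 1e-12)
  }
  expect_true(all(diag(W2) == 0))
  expect_error(correlation_matrix(cbind(rnorm(10), rep(1, 10))), "constant")
})

test_that("validate_structural enforces symmetry, nonnegativity and the diagonal rule", {
  m <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3)
  ok <- validate_structural(m)
  expect_equal(ok$weights, m)
  expect_identical(ok$modality, "dmri")
  bad_neg <- m; bad_neg[1, 2] <- bad_neg[2, 1] <- -1
  expect_error(validate_structural(bad_neg), "negative")
  bad_asym <- m; bad_asym[1, 2] <- 9
  expect_error(validate_structural(bad_asym), "asymmetric")
  near <- m; diag(near) <- 1e-12
  expect_equal(diag(validate_structural(near)$weights), rep(0, 3))
  far <- m; diag(far) <- 1
  expect_error(validate_structural(far), "diagonal")
})

test_that("exclude_regions removes regions globally and keeps submatrices intact", {
  set.seed(9)
  w <- random_weighted_graph(210)
  cm <- connectivity_matrix(w, "dmri")
  bad <- sort(sample(210, 13))
  out <- exclude_regions(cm, bad)
  expect_equal(nrow(out$weights), 197)
  expect_equal(out$weights, w[-bad, -bad])
  # nested subject/layer lists are handled uniformly
  subj <- list(s1 = list(a = cm, b = connectivity_matrix(w, "rsfmri")))
  out2 <- exclude_regions(subj, bad)
  expect_equal(out2$s1$b$weights, w[-bad, -bad])
  # empty exclusion is the identity
  expect_identical(exclude_regions(cm, integer(0)), cm)
  # atlas rows are dropped and reindexed
  atlas <- make_atlas(210, c(VN = 30, SMN = 30, DAN = 30, VAN = 30,
                             LMN = 30, FPN = 30, DMN = 30))
  a2 <- exclude_regions(atlas, bad)
  expect_equal(nrow(a2), 197)
  expect_equal(a2$region_index, 0:196)
  expect_error(exclude_regions(cm, c(1, 999)), "out of range")
})
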