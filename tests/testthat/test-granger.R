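test_that("min-max normalization maps extremes to -1/+1", {
  expect_equal(as.numeric(normalize_signal(c(0, 5, 10))), c(-1, 0, 1))
  expect_equal(as.numeric(normalize_signal(c(-3, -3, 3))), c(-1, -1, 1))
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(50, sd = runif(1, 0.1, 10))
    nx <- normalize_signal(x)
    expect_equal(min(nx), -1)
    expect_equal(max(nx), 1)
    expect_identical(attr(nx, "e_min"), min(x))
  }
  expect_error(normalize_signal(rep(2, 10)), "zero dynamic range")
  expect_error(normalize_signal(3), "at least 2")
  expect_error(normalize_signal(c(1, NA, 3)), "non-finite")
})

test_that("the F-statistic matches independent oracles on random pairs", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(100:400, 1)
    p <- sample(1:4, 1)
    x <- rnorm(n)
    y <- as.numeric(stats::filter(0.4 * x + rnorm(n), 0.3,
                                  method = "recursive"))
    fit <- granger_f(x, y, lags = p)
    expect_equal(fit$statistic, bf_granger_f(x, y, p),
                 tolerance = 1e-6)
    # and the textbook implementation in lmtest agrees
    lt <- lmtest::grangertest(y ~ x, order = p)
    expect_equal(fit$statistic, lt$F[2], tolerance = 1e-6)
  }
})

test_that("a strong lagged coupling is detected in the right direction", {
  set.seed(7)
  x <- rnorm(1024)
  y <- c(0, 0.9 * x[-1024]) + rnorm(1024, sd = 0.09)
  fwd <- granger_f(x, y, lags = 1)
  rev <- granger_f(y, x, lags = 1)
  expect_gt(fwd$statistic, 60)
  expect_lt(rev$statistic, 60)
  expect_true(fwd$causal)
  # time reversal flips the dominant direction
  fwd_r <- granger_f(rev(x), rev(y), lags = 1)
  rev_r <- granger_f(rev(y), rev(x), lags = 1)
  expect_gt(rev_r$statistic, fwd_r$statistic)
})

test_that("F is invariant to affine rescaling of either signal", {
  set.seed(3)
  x <- rnorm(300)
  y <- as.numeric(stats::filter(0.5 * x + rnorm(300), 0.4,
                                method = "recursive"))
  f0 <- granger_f(x, y, lags = 2)$statistic
  expect_equal(granger_f(5 * x - 2, -3 * y + 7, lags = 2)$statistic, f0,
               tolerance = 1e-8)
  expect_equal(granger_f(as.numeric(normalize_signal(x)),
                         as.numeric(normalize_signal(y)),
                         lags = 2)$statistic, f0, tolerance = 1e-8)
})

test_that("model nesting and degenerate designs behave as required", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(120)
    y <- rnorm(120)
    fit <- granger_f(x, y, lags = sample(1:5, 1))
    expect_lte(fit$rss_unrestricted, fit$rss_restricted)
    expect_gte(fit$statistic, 0)
  }
  x <- rnorm(100)
  expect_error(granger_f(x, x, lags = 1), "collinear")
  expect_error(granger_f(rnorm(10), rnorm(10), lags = 4), "too short")
  expect_error(granger_f(rnorm(10), rnorm(12), lags = 1), "equal length")
})

test_that("BIC lag selection recovers the true order of a lagged coupling", {
  set.seed(31)
  x <- rnorm(2048)
  y <- c(0, 0, 0, 0.8 * x[1:2045]) + rnorm(2048, sd = 0.2)
  fit <- granger_f(x, y, lags = "bic", max_lag = 8)
  expect_identical(fit$lag, 3L)
  expect_gt(fit$statistic, 60)
})

test_that("white-noise pairs reject at roughly the nominal 5% rate", {
  set.seed(100)
  rej <- 0L
  n_mc <- 300
  for (i in seq_len(n_mc)) {
    fit <- granger_f(rnorm(256), rnorm(256), lags = 1)
    rej <- rej + fit$causal
  }
  expect_gt(rej / n_mc, 0.02)
  expect_lt(rej / n_mc, 0.09)
})

test_that("the connectivity matrix covers all ordered pairs, diagonal zero", {
  set.seed(12)
  s <- matrix(rnorm(6 * 400), 6)
  m <- connectivity_matrix(s, lags = 1)
  expect_identical(dim(m), c(6L, 6L))
  expect_true(all(diag(m) == 0))
  expect_identical(sum(unclass(m) != 0 | diag(6) == 1) - 6L, 30L)
  expect_true(all(m >= 0))
  # permutation equivariance: reordering signals permutes rows and columns
  perm <- c(3, 1, 6, 2, 5, 4)
  m2 <- connectivity_matrix(s[perm, ], lags = 1)
  expect_equal(unclass(m2), unclass(m)[perm, perm], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("orientation convention: column = source, row = target", {
  set.seed(17)
  x <- rnorm(800)
  y <- c(0, 0.9 * x[-800]) + rnorm(800, sd = 0.1)
  z <- rnorm(800)
  m <- connectivity_matrix(rbind(x, y, z), lags = 1)
  # signal 1 drives signal 2: the F lands at (target = 2, source = 1)
  expect_gt(m[2, 1], 60)
  expect_lt(m[1, 2], 60)
})

test_that("a failing cell yields F = 0 with a warning, not an abort", {
  set.seed(19)
  s <- rbind(rnorm(200), rnorm(200), rep(1, 200))   # constant third signal
  expect_warning(m <- connectivity_matrix(s, lags = 1), "zero dynamic range")
  expect_true(all(m[3, ] == 0) && all(m[, 3] == 0))
  expect_gte(attr(m, "failed"), 1L)
  expect_true(any(unclass(m)[1:2, 1:2] != 0))
})
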