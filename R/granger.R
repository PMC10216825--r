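# Min-max normalization and pairwise Granger-causality F-statistics.

#' Min-max normalize a signal to [-1, 1]
#'
#' Affine map `x = 2 * (e - e_min) / (e_max - e_min) - 1` sending the signal
#' minimum to -1 and the maximum to +1. The source extrema are kept as
#' attributes `e_min` / `e_max` so the map is invertible.
#'
#' @param signal Finite numeric vector of length >= 2.
#' @return Normalized numeric vector with attributes `e_min`, `e_max`.
#' @export
#' @examples
#' normalize_signal(c(0, 5, 10))   # -1 0 1
normalize_signal <- function(signal) {
  signal <- as.numeric(signal)
  if (length(signal) < 2L) stopf("signal must have at least 2 samples")
  if (!all(is.finite(signal))) stopf("signal contains non-finite values")
  e_min <- min(signal)
  e_max <- max(signal)
  if (e_max == e_min) {
    stopf("zero dynamic range: constant signal cannot be min-max normalized")
  }
  out <- 2 * (signal - e_min) / (e_max - e_min) - 1
  attr(out, "e_min") <- e_min
  attr(out, "e_max") <- e_max
  out
}

# Build lagged design matrices for the pair (x, y) at lag p, dropping the
# first p samples. Returns response, restricted and unrestricted designs.
.gc_design <- function(x, y, p) {
  n <- length(y)
  emb <- stats::embed(cbind(y, x), p + 1L)
  resp <- emb[, 1L]
  ylags <- emb[, 2L * seq_len(p) + 1L, drop = FALSE]
  xlags <- emb[, 2L * seq_len(p) + 2L, drop = FALSE]
  list(resp = resp,
       Xr = cbind(1, ylags),
       Xu = cbind(1, ylags, xlags),
       n_eff = n - p)
}

.rss_fit <- function(X, y) {
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

# Core F computation at a fixed lag; assumes preconditions checked.
.granger_fixed <- function(x, y, p) {
  d <- .gc_design(x, y, p)
  if (qr(d$Xu)$rank < ncol(d$Xu)) {
    stopf("collinear design: lagged regressors of the pair are rank-deficient at lag %d", p)
  }
  rss_r <- .rss_fit(d$Xr, d$resp)
  rss_u <- .rss_fit(d$Xu, d$resp)
  df2 <- d$n_eff - 2L * p - 1L
  f <- ((rss_r - rss_u) / p) / (rss_u / df2)
  list(F = max(f, 0), p = p, n_eff = d$n_eff,
       rss_r = rss_r, rss_u = rss_u, df1 = p, df2 = df2)
}

# Select the lag in 1..max_lag minimizing the BIC of the unrestricted model,
# compared on the common sample (first max_lag points dropped).
.select_lag_bic <- function(x, y, max_lag) {
  n <- length(y)
  emb <- stats::embed(cbind(y, x), max_lag + 1L)
  resp <- emb[, 1L]
  nc <- n - max_lag
  best_p <- 1L
  best_bic <- Inf
  for (p in seq_len(max_lag)) {
    ylags <- emb[, 2L * seq_len(p) + 1L, drop = FALSE]
    xlags <- emb[, 2L * seq_len(p) + 2L, drop = FALSE]
    Xu <- cbind(1, ylags, xlags)
    rss <- .rss_fit(Xu, resp)
    bic <- nc * log(rss / nc) + (2 * p + 1) * log(nc)
    if (bic < best_bic - 1e-12) {
      best_bic <- bic
      best_p <- p
    }
  }
  best_p
}

#' Granger-causality F-test for "x causes y"
#'
#' Fits, by ordinary least squares on the common sample (first `p` points
#' dropped), the restricted autoregression of `y` on its own `p` lags plus an
#' intercept, and the unrestricted model adding `p` lags of `x`. The
#' statistic is
#' `F = ((RSS_r - RSS_u) / p) / (RSS_u / (n_eff - 2p - 1))`,
#' distributed as F(p, n_eff - 2p - 1) under the null that `x`'s past adds
#' no predictive information about `y`.
#'
#' @param x,y Equal-length numeric signals; the test direction is x -> y.
#' @param lags Either `"bic"` (default: pick the lag in `1..max_lag`
#'   minimizing the unrestricted model's BIC on a common sample) or a fixed
#'   positive integer.
#' @param max_lag Upper lag bound for BIC selection (default 20).
#' @param alpha Significance level for the derived binary causality
#'   indicator.
#' @return A `gc_fit` object: list with `statistic` (F), `lag`,
#'   `n_effective`, `rss_restricted`, `rss_unrestricted`, `df1`, `df2`,
#'   `p_value`, `critical` (upper alpha quantile) and `causal` (logical,
#'   `statistic > critical`).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(512)
#' y <- c(0, 0.9 * x[-512]) + rnorm(512, sd = 0.1)
#' granger_f(x, y, lags = 1)$statistic
granger_f <- function(x, y, lags = "bic", max_lag = 20, alpha = 0.05) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stopf("signals contain non-finite values")
  }
  if (identical(lags, "bic")) {
    max_lag <- as.integer(max_lag)
    if (length(y) <= 3L * max_lag + 2L) {
      max_lag <- max(1L, (length(y) - 3L) %/% 3L)
    }
    p <- .select_lag_bic(x, y, max_lag)
  } else {
    if (!is_scalar_number(lags) || lags < 1 || lags != round(lags)) {
      stopf("`lags` must be \"bic\" or a positive integer")
    }
    p <- as.integer(lags)
  }
  if (length(y) <= 3L * p + 2L) {
    stopf("signal length %d too short for lag %d (need > %d)",
          length(y), p, 3L * p + 2L)
  }
  res <- .granger_fixed(x, y, p)
  crit <- stats::qf(1 - alpha, res$df1, res$df2)
  structure(
    list(statistic = res$F, lag = res$p, n_effective = res$n_eff,
         rss_restricted = res$rss_r, rss_unrestricted = res$rss_u,
         df1 = res$df1, df2 = res$df2,
         p_value = stats::pf(res$F, res$df1, res$df2, lower.tail = FALSE),
         critical = crit, causal = res$F > crit),
    class = "gc_fit"
  )
}

#' @export
print.gc_fit <- function(x, ...) {
  cat(sprintf(
    "Granger causality: F(%d, %d) = %.4f, lag = %d, p-value = %.4g\n",
    x$df1, x$df2, x$statistic, x$lag, x$p_value))
  cat(sprintf("  RSS restricted %.6g, unrestricted %.6g; causal at 5%%: %s\n",
              x$rss_restricted, x$rss_unrestricted, x$causal))
  invisible(x)
}

#' Directed Granger-causality connectivity matrix
#'
#' Computes the pairwise F-statistic for every ordered pair of signals after
#' min-max normalizing each signal. Orientation convention: element (i, j)
#' holds the statistic for the test "signal j Granger-causes signal i"
#' (column = source, row = target). The diagonal is stored as 0 and is never
#' thresholded. A failing cell (e.g. a constant or collinear signal) yields
#' F = 0 with a warning instead of aborting the matrix.
#'
#' @param signals Numeric matrix (signals in rows) or list of equal-length
#'   numeric vectors. Row/element names label the matrix.
#' @param lags,max_lag Lag policy passed to [granger_f()].
#' @param normalize Apply [normalize_signal()] to each signal first
#'   (default TRUE).
#' @return A `gc_matrix`: square numeric matrix with attributes `lag`
#'   (matrix of per-pair lags used) and `failed` (count of failed cells).
#' @export
#' @examples
#' set.seed(1)
#' s <- matrix(rnorm(3 * 256), 3)
#' connectivity_matrix(s, lags = 1)
connectivity_matrix <- function(signals, lags = "bic", max_lag = 20,
                                normalize = TRUE) {
  if (is.list(signals)) {
    signals <- do.call(rbind, lapply(signals, as.numeric))
  }
  signals <- as.matrix(signals)
  n <- nrow(signals)
  if (n < 2L) stopf("need at least 2 signals")
  nm <- rownames(signals) %||% paste0("S", seq_len(n))
  sig <- vector("list", n)
  bad <- rep(FALSE, n)
  for (i in seq_len(n)) {
    sig[[i]] <- if (normalize) {
      tryCatch(as.numeric(normalize_signal(signals[i, ])),
               error = function(e) {
                 warnf("signal %s: %s (its cells set to 0)", nm[i],
                       conditionMessage(e))
                 bad[i] <<- TRUE
                 NULL
               })
    } else {
      signals[i, ]
    }
  }
  M <- matrix(0, n, n, dimnames = list(target = nm, source = nm))
  P <- matrix(NA_integer_, n, n, dimnames = list(target = nm, source = nm))
  failed <- sum(bad)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || bad[i] || bad[j]) next
      fit <- tryCatch(
        granger_f(sig[[j]], sig[[i]], lags = lags, max_lag = max_lag),
        error = function(e) {
          warnf("cell (%s <- %s): %s (F set to 0)", nm[i], nm[j],
                conditionMessage(e))
          NULL
        })
      if (is.null(fit)) {
        failed <- failed + 1L
      } else {
        M[i, j] <- fit$statistic
        P[i, j] <- fit$lag
      }
    }
  }
  structure(M, lag = P, failed = failed, class = c("gc_matrix", "matrix"))
}

#' @export
print.gc_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<gc_matrix> %d x %d (row = target, column = source)\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Heat-map of a connectivity matrix
#'
#' @param x A `gc_matrix`.
#' @param main Plot title.
#' @param ... Further arguments to [graphics::image()].
#' @export
plot.gc_matrix <- function(x, main = "Granger causality (F)", ...) {
  m <- unclass(x)
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "source", ylab = "target",
                  main = main, ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Write a connectivity matrix as CSV
#'
#' @param m A `gc_matrix` (or plain square matrix).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
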