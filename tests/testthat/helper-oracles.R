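# Independent oracles and small fixture builders used across tests.

# Brute-force Granger F via explicit normal equations (no shared code with
# the package's QR-based fit): restricted and unrestricted OLS solved with
# solve(t(X) %*% X, t(X) %*% y) on the common sample.
bf_granger_f <- function(x, y, p) {
  n <- length(y)
  idx <- (p + 1):n
  ylags <- sapply(1:p, function(l) y[idx - l])
  xlags <- sapply(1:p, function(l) x[idx - l])
  resp <- y[idx]
  rss_of <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% resp)
    sum((resp - X %*% beta)^2)
  }
  Xr <- cbind(1, ylags)
  Xu <- cbind(Xr, xlags)
  rss_r <- rss_of(Xr)
  rss_u <- rss_of(Xu)
  n_eff <- n - p
  ((rss_r - rss_u) / p) / (rss_u / (n_eff - 2 * p - 1))
}

# A tiny generic montage: 4 channels in 2 areas, nothing unassigned.
tiny_montage <- function() {
  montage(list(L = c("c1", "c2"), R = c("c3", "c4")), name = "tiny")
}

rand_trial <- function(n_ch = 32, n_samples = 256, fs = 128, seed = 1,
                       channels = deap_channels()) {
  with_seed <- function(s, expr) { set.seed(s); expr }
  with_seed(seed, eeg_trial(matrix(rnorm(n_ch * n_samples), n_ch),
                            fs = fs, channel_names = channels[seq_len(n_ch)]))
}

# A feature table with disjoint per-class value clusters (perfectly
# separable one-dimensional problem).
separable_features <- function(n_per_class = 32, seed = 1) {
  set.seed(seed)
  centers <- c(-0.75, -0.25, 0.25, 0.75)
  cls <- rep(1:4, each = n_per_class)
  x <- centers[cls] + runif(length(cls), -0.1, 0.1)
  out <- data.frame(
    subject_id = "s01", trial_id = sprintf("t%03d", seq_along(cls)),
    class_id = cls, quantifier_raw = x, quantifier_norm = x,
    band = "all", mode = "areas", stringsAsFactors = FALSE)
  class(out) <- c("gc_features", "data.frame")
  out
}
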