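# Synthetic multichannel EEG with known directed coupling: a stationary
# vector autoregression over six latent area nodes, mixed onto the
# 32-channel reference montage with sensor noise and band-limited
# oscillatory content. Ground truth for every downstream pipeline stage.

#' Specify a VAR coupling structure
#'
#' Builds the lag-coefficient array of an `n_nodes`-dimensional vector
#' autoregression: each node carries a self-lag (autocorrelation) and each
#' directed link `(source, target, strength)` adds a lag-1 cross coefficient.
#' The spec is rejected unless the companion matrix is stable (spectral
#' radius < 1).
#'
#' @param n_nodes Number of latent nodes; default 6 (one per brain area).
#' @param p Lag order of the process; default 1.
#' @param links List of numeric triples `c(source, target, strength)`.
#' @param self Self-lag coefficient applied to every node at lag 1.
#' @param sigma Innovation standard deviation, scalar or per node.
#' @return A `coupling_spec`: list with the coefficient array `A`
#'   (n x n x p), `sigma`, `links` and the companion spectral radius.
#' @export
#' @examples
#' coupling_spec(links = list(c(1, 3, 0.8)))$radius
coupling_spec <- function(n_nodes = 6, p = 1, links = list(), self = 0.5,
                          sigma = 1) {
  n <- as.integer(n_nodes)
  p <- as.integer(p)
  if (n < 1L || p < 1L) stopf("n_nodes and p must be positive")
  A <- array(0, dim = c(n, n, p))
  A[, , 1][cbind(seq_len(n), seq_len(n))] <- self
  for (lk in links) {
    if (length(lk) != 3L) stopf("each link must be c(source, target, strength)")
    src <- as.integer(lk[1]); tgt <- as.integer(lk[2])
    if (src < 1L || src > n || tgt < 1L || tgt > n || src == tgt) {
      stopf("link %d -> %d outside 1..%d or self-link", src, tgt, n)
    }
    A[tgt, src, 1L] <- A[tgt, src, 1L] + lk[3]
  }
  # companion matrix of the VAR(p): stability iff spectral radius < 1
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) comp[seq_len(n), (l - 1) * n + seq_len(n)] <- A[, , l]
  if (p > 1L) {
    comp[n + seq_len(n * (p - 1)), seq_len(n * (p - 1))] <-
      diag(n * (p - 1))
  }
  radius <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (radius >= 1) {
    stopf("non-stationary coupling spec: companion spectral radius %.4f >= 1",
          radius)
  }
  structure(
    list(n_nodes = n, p = p, A = A, sigma = rep_len(sigma, n),
         links = links, radius = radius),
    class = "coupling_spec"
  )
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("<coupling_spec> %d nodes, VAR(%d), spectral radius %.3f\n",
              x$n_nodes, x$p, x$radius))
  for (lk in x$links) {
    cat(sprintf("  node %d -> node %d (strength %.2f)\n",
                lk[1], lk[2], lk[3]))
  }
  invisible(x)
}

#' Simulate the latent VAR node series
#'
#' @param spec A [coupling_spec()].
#' @param n_samples Series length after burn-in.
#' @param seed Integer seed; identical seeds give identical series.
#' @param burn_in Samples discarded from the start (default 200).
#' @return Numeric matrix, `n_nodes` x `n_samples`.
#' @export
generate_var_series <- function(spec, n_samples, seed = 1, burn_in = 200) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (n_samples < 10 * spec$p) {
    stopf("n_samples must be at least 10 x lag order (%d)", 10 * spec$p)
  }
  n <- spec$n_nodes
  p <- spec$p
  total <- n_samples + burn_in
  with_seed(seed, {
    e <- matrix(stats::rnorm(n * total, sd = spec$sigma), n, total)
    y <- matrix(0, n, total)
    for (t in seq_len(total)) {
      acc <- e[, t]
      for (l in seq_len(min(p, t - 1))) {
        acc <- acc + spec$A[, , l] %*% y[, t - l]
      }
      y[, t] <- acc
    }
    y[, burn_in + seq_len(n_samples), drop = FALSE]
  })
}

#' Generate one synthetic 32-channel trial
#'
#' Simulates the latent VAR, adds per-node amplitude-modulated sinusoidal
#' carriers at the band-center frequencies (2, 12, 24, 48 Hz; independent
#' phases per node, so the carriers add band energy without cross-node
#' predictability), then mixes nodes onto the montage: every channel of an
#' area carries its area's node plus independent white sensor noise at the
#' requested signal-to-noise ratio. Midline (unassigned) channels carry the
#' mean of all nodes plus noise.
#'
#' @param spec A [coupling_spec()] with one node per montage area.
#' @param n_samples Samples per channel; default 8064 (63 s at 128 Hz).
#' @param fs Sampling rate in Hz; default 128.
#' @param seed Integer seed; trials are deterministic given the seed.
#' @param montage An [eeg_montage]; default [deap_montage()].
#' @param band_amp Named amplitudes of the delta/alpha/beta/gamma carriers.
#' @param snr_db Sensor signal-to-noise ratio in dB; default 10.
#' @param subject_id,trial_id Identifiers for the produced trial.
#' @return An [eeg_trial] with the montage's full channel set.
#' @export
generate_var_trial <- function(spec, n_samples = 8064, fs = 128, seed = 1,
                               montage = deap_montage(),
                               band_amp = c(delta = 0.5, alpha = 0.5,
                                            beta = 0.5, gamma = 0.5),
                               snr_db = 10,
                               subject_id = "s01", trial_id = "t01") {
  stopifnot(inherits(montage, "eeg_montage"))
  if (spec$n_nodes != length(montage$areas)) {
    stopf("spec has %d nodes but montage defines %d areas",
          spec$n_nodes, length(montage$areas))
  }
  nodes <- generate_var_series(spec, n_samples, seed = seed)
  carriers_hz <- c(delta = 2, alpha = 12, beta = 24, gamma = 48)
  tt <- seq_len(n_samples) / fs
  with_seed(derive_seed(seed, 1L), {
    for (i in seq_len(spec$n_nodes)) {
      for (b in names(carriers_hz)) {
        amp <- band_amp[[b]] %||% 0
        if (amp == 0) next
        # node-specific frequency offset: deterministic carriers at one
        # shared frequency would be linearly cross-predictable and fake
        # causal links, so each node oscillates slightly apart
        f <- carriers_hz[[b]] * (1 + 0.015 * (i - (spec$n_nodes + 1) / 2))
        phase <- stats::runif(1, 0, 2 * pi)
        env <- 0.5 * (1 + sin(2 * pi * 0.2 * tt + stats::runif(1, 0, 2 * pi)))
        nodes[i, ] <- nodes[i, ] +
          amp * env * sin(2 * pi * f * tt + phase)
      }
    }
    channels <- c(unlist(montage$areas), montage$unassigned)
    area_of <- rep(seq_along(montage$areas), lengths(montage$areas))
    mat <- matrix(0, length(channels), n_samples)
    noise_sd <- sqrt(mean(apply(nodes, 1, stats::var)) / 10^(snr_db / 10))
    for (ci in seq_along(channels)) {
      src <- if (ci <= length(area_of)) {
        nodes[area_of[ci], ]
      } else {
        colMeans(nodes)
      }
      mat[ci, ] <- src + stats::rnorm(n_samples, sd = noise_sd)
    }
    # restore the canonical montage channel order
    canon <- if (setequal(channels, deap_channels())) {
      deap_channels()
    } else {
      channels
    }
    mat <- mat[match(canon, channels), , drop = FALSE]
    eeg_trial(mat, fs = fs, channel_names = canon,
              subject_id = subject_id, trial_id = trial_id)
  })
}

#' Per-class synthetic coupling specifications
#'
#' The four emotion classes are encoded by graded directed inter-area
#' coupling: class 1 (LALV) carries the strongest and most numerous links,
#' class 4 (HAHV) none. Strengths are chosen for clear parameter recovery —
#' well-ordered connectivity quantifiers — not to mimic any real dataset.
#' Each class also carries the valence/arousal sampling rectangle consistent
#' with its quadrant (kept clear of the 4.5 boundary).
#'
#' @return Named list of 4 `class_spec` lists, each with `class_id`,
#'   `coupling` (a [coupling_spec()]), `valence_range`, `arousal_range`.
#' @export
class_specs_default <- function() {
  lo <- c(1, 4.4)
  hi <- c(4.6, 9)
  mk <- function(id, links, vr, ar) {
    list(class_id = id,
         coupling = coupling_spec(n_nodes = 6, p = 1, links = links),
         valence_range = vr, arousal_range = ar)
  }
  list(
    class1 = mk(1L, list(c(1, 3, 0.9), c(3, 5, 0.85), c(2, 4, 0.8)), lo, lo),
    class2 = mk(2L, list(c(1, 3, 0.65), c(2, 4, 0.6)), lo, hi),
    class3 = mk(3L, list(c(1, 3, 0.5)), hi, lo),
    class4 = mk(4L, list(), hi, hi)
  )
}

#' Generate a labelled synthetic recording set
#'
#' Trials cycle through the four classes (trial j of every subject gets
#' class `((j - 1) mod 4) + 1`), valence/arousal scores are sampled
#' uniformly inside each class's quadrant rectangle, and every trial is
#' regenerable in isolation: trial (i, j) uses the child seed
#' `derive_seed(seed, i, j)` of the single master seed.
#'
#' @param n_subjects,n_trials_per_subject Dataset dimensions.
#' @param class_specs Per-class specifications; default
#'   [class_specs_default()].
#' @param seed Master seed.
#' @param n_samples,fs,snr_db,montage Passed to [generate_var_trial()].
#' @param balanced Require at least one trial per class (default TRUE);
#'   errors when `n_trials_per_subject` is below the number of classes.
#' @return A [recording_set] with `n_subjects * n_trials_per_subject`
#'   trials.
#' @export
#' @examples
#' rs <- generate_dataset(1, 4, seed = 7, n_samples = 256)
#' rs$labels$class_id
generate_dataset <- function(n_subjects, n_trials_per_subject,
                             class_specs = class_specs_default(), seed = 1,
                             n_samples = 8064, fs = 128, snr_db = 10,
                             montage = deap_montage(), balanced = TRUE) {
  n_cls <- length(class_specs)
  if (balanced && n_trials_per_subject < n_cls) {
    stopf("balanced allocation needs at least %d trials per subject, got %d",
          n_cls, n_trials_per_subject)
  }
  trials <- vector("list", n_subjects * n_trials_per_subject)
  lab <- vector("list", length(trials))
  k <- 0L
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(n_trials_per_subject)) {
      k <- k + 1L
      cs <- class_specs[[((j - 1L) %% n_cls) + 1L]]
      child <- derive_seed(seed, i, j)
      sid <- sprintf("s%02d", i)
      tid <- sprintf("t%02d", j)
      trials[[k]] <- generate_var_trial(
        cs$coupling, n_samples = n_samples, fs = fs, seed = child,
        montage = montage, snr_db = snr_db,
        subject_id = sid, trial_id = tid)
      scores <- with_seed(derive_seed(seed, i, j, 2L), c(
        stats::runif(1, cs$valence_range[1], cs$valence_range[2]),
        stats::runif(1, cs$arousal_range[1], cs$arousal_range[2])))
      lab[[k]] <- data.frame(subject_id = sid, trial_id = tid,
                             valence = scores[1], arousal = scores[2],
                             class_id = cs$class_id,
                             stringsAsFactors = FALSE)
    }
  }
  recording_set(trials, do.call(rbind, lab), name = "synthetic_var",
                montage_id = montage$name)
}
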