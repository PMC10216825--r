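# The scalar connectivity quantifier: thresholded sum of suprathreshold
# F-values, and its per-trial feature vector over a recording set.

#' Thresholded-sum quantifier of a connectivity matrix
#'
#' Sums every off-diagonal F-value strictly greater than the threshold (the
#' diagonal is never considered; an entry exactly at the threshold is
#' excluded). Returns 0 when no entry qualifies. The sum runs over the full
#' directed matrix, both triangles.
#'
#' @param m Square numeric matrix (typically a `gc_matrix`).
#' @param threshold Positive F-value cut; default 60.
#' @return Scalar, `sum(F[F > threshold])` over off-diagonal cells.
#' @export
#' @examples
#' m <- matrix(0, 6, 6)
#' m[1, 3] <- 101.54; m[6, 3] <- 91.93; m[6, 1] <- 68.17
#' quantify(m)   # 261.64
quantify <- function(m, threshold = 60) {
  m <- as.matrix(unclass(m))
  if (nrow(m) != ncol(m)) stopf("connectivity matrix must be square")
  if (!is_scalar_number(threshold) || threshold <= 0) {
    stopf("threshold must be a positive number")
  }
  off <- m[row(m) != col(m)]
  sum(off[off > threshold])
}

#' Build the per-trial scalar feature vector for a recording set
#'
#' Runs the full feature chain per trial: band extraction (channel-wise
#' wavelet reconstruction; band `"all"` passes the raw signal), optional
#' combination into brain-area averages, min-max normalization of each
#' signal, the pairwise Granger connectivity matrix, and the thresholded-sum
#' quantifier. The resulting raw vector (one scalar per trial) is then
#' itself min-max normalized to [-1, 1] for classification.
#'
#' A trial whose feature computation fails is dropped together with its
#' label, with a warning naming the trial.
#'
#' @param recordings A [recording_set].
#' @param band Band name (see [default_bands()]); default `"all"`.
#' @param mode `"areas"` (6 area signals via the montage) or `"channels"`
#'   (all montage channels).
#' @param montage An [eeg_montage]; default [deap_montage()].
#' @param threshold Quantifier F-cut; default 60.
#' @param lags,max_lag Lag policy for [granger_f()].
#' @param wavelet_order,level Wavelet parameters for band extraction.
#' @return A `gc_features` data frame with columns `subject_id`, `trial_id`,
#'   `class_id`, `quantifier_raw`, `quantifier_norm`, `band`, `mode`.
#' @export
build_feature_vector <- function(recordings, band = "all",
                                 mode = c("areas", "channels"),
                                 montage = deap_montage(), threshold = 60,
                                 lags = "bic", max_lag = 20,
                                 wavelet_order = 4, level = 5) {
  stopifnot(inherits(recordings, "recording_set"))
  mode <- match.arg(mode)
  needed <- unique(c(unlist(montage$areas), montage$unassigned))
  miss <- setdiff(needed, recordings$channel_names)
  if (length(miss)) {
    stopf("montage mismatch in mode '%s': recording set lacks channel(s) %s",
          mode, paste(miss, collapse = ", "))
  }
  n <- length(recordings$trials)
  raw <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- recordings$trials[[i]]
    val <- tryCatch({
      dat <- if (band == "all") {
        tr$data
      } else {
        t(apply(tr$data, 1, extract_band, fs = tr$fs, band = band,
                wavelet_order = wavelet_order, level = level))
      }
      bt <- eeg_trial(dat, fs = tr$fs, channel_names = tr$channel_names,
                      subject_id = tr$subject_id, trial_id = tr$trial_id)
      sig <- if (mode == "areas") combine_areas(bt, montage)$data else bt$data
      cm <- connectivity_matrix(sig, lags = lags, max_lag = max_lag)
      quantify(cm, threshold)
    }, error = function(e) {
      warnf("trial %s/%s dropped: %s", tr$subject_id, tr$trial_id,
            conditionMessage(e))
      NA_real_
    })
    raw[i] <- val
  }
  keep <- !is.na(raw)
  lab <- recordings$labels[keep, , drop = FALSE]
  raw <- raw[keep]
  norm <- as.numeric(normalize_signal(raw))
  out <- data.frame(
    subject_id = lab$subject_id, trial_id = lab$trial_id,
    class_id = lab$class_id, quantifier_raw = raw, quantifier_norm = norm,
    band = band, mode = mode, stringsAsFactors = FALSE
  )
  class(out) <- c("gc_features", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Write a feature vector as CSV
#'
#' @param features A `gc_features` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature vector written by [write_features()]
#'
#' @param path CSV file path.
#' @return A `gc_features` data frame.
#' @export
read_features <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_id", "class_id", "quantifier_raw",
            "quantifier_norm")
  if (!all(need %in% names(out))) {
    stopf("feature file lacks column(s): %s",
          paste(setdiff(need, names(out)), collapse = ", "))
  }
  class(out) <- c("gc_features", "data.frame")
  out
}
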