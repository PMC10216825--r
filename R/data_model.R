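# Core data model: single trials, label records, recording sets, and the
# plain-text on-disk layout.

#' Construct an EEG trial
#'
#' The atomic unit of processing: one channels-by-samples numeric matrix with
#' its sampling rate and channel labels.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one label per row of `data`.
#' @param subject_id,trial_id Identifier strings.
#' @return An object of class `eeg_trial`.
#' @export
#' @examples
#' tr <- eeg_trial(matrix(rnorm(4 * 64), 4), fs = 128,
#'                 channel_names = c("a", "b", "c", "d"))
#' dim(tr$data)
eeg_trial <- function(data, fs, channel_names,
                      subject_id = "s01", trial_id = "t01") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stopf("trial data must be numeric")
  if (nrow(data) != length(channel_names)) {
    stopf("trial has %d rows but %d channel names",
          nrow(data), length(channel_names))
  }
  if (!is_scalar_number(fs) || fs <= 0) stopf("fs must be a positive number")
  if (ncol(data) < 4L) stopf("trial must have at least 4 samples")
  if (!all(is.finite(data))) {
    stopf("trial %s/%s contains non-finite values", subject_id, trial_id)
  }
  dimnames(data) <- list(channel_names, NULL)
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id)),
    class = "eeg_trial"
  )
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial %s/%s> %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$trial_id, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Map valence/arousal self-assessment scores to an emotion class
#'
#' The two-dimensional emotion model is cut at 4.5 on both axes ("low" is
#' strictly below 4.5, "high" is at or above 4.5), giving four quadrant
#' classes: 1 = LALV (low arousal, low valence), 2 = HALV, 3 = LAHV,
#' 4 = HAHV. Vectorized over both arguments.
#'
#' @param valence,arousal Numeric scores on the 1-9 self-assessment scale.
#' @return Integer class id(s) in 1..4.
#' @export
#' @examples
#' assign_class(valence = 3, arousal = 3)      # 1: LALV
#' assign_class(valence = 4.5, arousal = 4.5)  # 4: boundary is "high"
assign_class <- function(valence, arousal) {
  valence <- as.numeric(valence)
  arousal <- as.numeric(arousal)
  if (any(!is.finite(valence)) || any(valence < 1 | valence > 9)) {
    stopf("valence score out of range [1, 9]")
  }
  if (any(!is.finite(arousal)) || any(arousal < 1 | arousal > 9)) {
    stopf("arousal score out of range [1, 9]")
  }
  as.integer(1L + (arousal >= 4.5) + 2L * (valence >= 4.5))
}

#' Construct a recording set
#'
#' Bundles trials with their label records and manifest metadata. Every trial
#' must have exactly one label row (matched on subject and trial id), and all
#' trials must share the sampling rate and channel set.
#'
#' @param trials List of [eeg_trial] objects.
#' @param labels Data frame with columns `subject_id`, `trial_id`, `valence`,
#'   `arousal`; a `class_id` column is derived if absent.
#' @param name Dataset name.
#' @param montage_id Identifier of the montage the channels follow.
#' @return An object of class `recording_set`.
#' @export
recording_set <- function(trials, labels, name = "dataset",
                          montage_id = "deap32") {
  stopifnot(is.list(trials), is.data.frame(labels))
  need <- c("subject_id", "trial_id", "valence", "arousal")
  if (!all(need %in% names(labels))) {
    stopf("labels must have columns %s", paste(need, collapse = ", "))
  }
  if (length(trials) != nrow(labels)) {
    stopf("%d trials but %d label rows", length(trials), nrow(labels))
  }
  labels$subject_id <- as.character(labels$subject_id)
  labels$trial_id <- as.character(labels$trial_id)
  if (is.null(labels$class_id)) {
    labels$class_id <- assign_class(labels$valence, labels$arousal)
  }
  keys <- vapply(trials, function(tr) paste(tr$subject_id, tr$trial_id),
                 character(1))
  lab_keys <- paste(labels$subject_id, labels$trial_id)
  if (anyDuplicated(keys)) stopf("duplicate trial ids in recording set")
  if (!setequal(keys, lab_keys)) {
    bad <- c(setdiff(keys, lab_keys), setdiff(lab_keys, keys))
    stopf("trial/label mismatch for: %s", paste(bad, collapse = ", "))
  }
  labels <- labels[match(keys, lab_keys), , drop = FALSE]
  rownames(labels) <- NULL
  fs <- unique(vapply(trials, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L) stopf("trials disagree on sampling rate")
  ch <- trials[[1]]$channel_names
  same <- vapply(trials, function(tr) identical(tr$channel_names, ch),
                 logical(1))
  if (!all(same)) stopf("trials disagree on channel names/order")
  structure(
    list(trials = trials, labels = labels, name = name, fs = fs,
         montage_id = montage_id, channel_names = ch),
    class = "recording_set"
  )
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set '%s'> %d trials, %d channels @ %g Hz\n",
              x$name, length(x$trials), length(x$channel_names), x$fs))
  print(table(class = x$labels$class_id))
  invisible(x)
}

#' Write a recording set to the canonical plain-text layout
#'
#' Layout: `manifest.txt` (key: value lines), `labels.csv` with header
#' `subject_id,trial_id,valence,arousal`, and one `trials/<subject>_<trial>.csv`
#' per trial (first column `channel`, remaining columns samples).
#'
#' @param rs A `recording_set`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording_set <- function(rs, path) {
  stopifnot(inherits(rs, "recording_set"))
  dir.create(file.path(path, "trials"), recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    paste0("name: ", rs$name),
    paste0("fs: ", format(rs$fs, digits = 15)),
    paste0("montage: ", rs$montage_id),
    paste0("n_trials: ", length(rs$trials))
  ), file.path(path, "manifest.txt"))
  utils::write.csv(
    rs$labels[, c("subject_id", "trial_id", "valence", "arousal")],
    file.path(path, "labels.csv"), row.names = FALSE
  )
  for (tr in rs$trials) {
    df <- data.frame(channel = tr$channel_names,
                     format(tr$data, digits = 15, trim = TRUE,
                            scientific = TRUE),
                     check.names = FALSE)
    utils::write.csv(df, file.path(path, "trials",
                                   paste0(tr$subject_id, "_", tr$trial_id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a recording set from the canonical layout
#'
#' Trials are validated (shape, finiteness, channel coverage) and their
#' channel rows are permuted to the reference montage order so downstream
#' matrix indices are stable. Label rows with out-of-range scores are
#' rejected with a message stating how many were dropped; a label without a
#' trial file is an error.
#'
#' @param path Directory holding the canonical layout (see
#'   [write_recording_set()]).
#' @param channel_order Canonical channel ordering to permute to; defaults to
#'   [deap_channels()] when the stored channels match that set, otherwise the
#'   stored order is kept.
#' @return A `recording_set`.
#' @export
read_recording_set <- function(path, channel_order = NULL) {
  man_path <- file.path(path, "manifest.txt")
  if (!file.exists(man_path)) stopf("no manifest.txt under '%s'", path)
  man <- readLines(man_path, warn = FALSE)
  man_get <- function(key) {
    hit <- grep(paste0("^", key, ":"), man, value = TRUE)
    if (!length(hit)) stopf("manifest misses key '%s'", key)
    trimws(sub("^[^:]*:", "", hit[1]))
  }
  fs <- as.numeric(man_get("fs"))
  labels <- utils::read.csv(file.path(path, "labels.csv"),
                            stringsAsFactors = FALSE)
  ok <- is.finite(labels$valence) & labels$valence >= 1 & labels$valence <= 9 &
    is.finite(labels$arousal) & labels$arousal >= 1 & labels$arousal <= 9
  if (any(!ok)) {
    message(sprintf("dropping %d label row(s) with invalid scores", sum(!ok)))
    labels <- labels[ok, , drop = FALSE]
  }
  if (!nrow(labels)) stopf("no valid label rows in '%s'", path)
  trials <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    sid <- as.character(labels$subject_id[i])
    tid <- as.character(labels$trial_id[i])
    f <- file.path(path, "trials", paste0(sid, "_", tid, ".csv"))
    if (!file.exists(f)) stopf("missing trial file '%s' for trial %s/%s",
                               f, sid, tid)
    df <- utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "channel") {
      stopf("trial file '%s' lacks leading 'channel' column", f)
    }
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    ch <- as.character(df$channel)
    ord <- channel_order
    if (is.null(ord) && all(ch %in% deap_channels())) ord <- deap_channels()
    if (!is.null(ord)) {
      miss <- setdiff(ord, ch)
      if (length(miss)) {
        stopf("trial %s/%s in '%s' is missing channel(s): %s",
              sid, tid, f, paste(miss, collapse = ", "))
      }
      mat <- mat[match(ord, ch), , drop = FALSE]
      ch <- ord
    }
    trials[[i]] <- eeg_trial(mat, fs = fs, channel_names = ch,
                             subject_id = sid, trial_id = tid)
  }
  recording_set(trials, labels, name = man_get("name"),
                montage_id = man_get("montage"))
}

#' Adapt an in-memory DEAP-shaped array to a recording set
#'
#' Accepts a numeric array of shape subjects x trials x channels x samples
#' (the layout of the preprocessed benchmark export) together with a
#' per-subject list or array of trial x 4 label scores whose first two
#' columns are valence and arousal. A 40-row channel axis is allowed: only
#' the first 32 rows are EEG; the peripheral rows are dropped with a warning.
#'
#' @param data 4-d numeric array, subjects x trials x channels x samples.
#' @param labels Numeric array subjects x trials x >=2 with valence and
#'   arousal in the first two columns of the last axis.
#' @param fs Sampling rate in Hz (128 for the reference export).
#' @param channel_names Labels for the EEG channels; default [deap_channels()].
#' @return A `recording_set`.
#' @export
deap_array_to_recording_set <- function(data, labels, fs = 128,
                                        channel_names = deap_channels()) {
  d <- dim(data)
  if (length(d) != 4L) stopf("expected a 4-d subjects x trials x channels x samples array")
  n_ch <- length(channel_names)
  if (d[3] == n_ch + 8L) {
    warnf("dropping %d peripheral (non-EEG) channel rows", d[3] - n_ch)
    data <- data[, , seq_len(n_ch), , drop = FALSE]
  } else if (d[3] != n_ch) {
    stopf("channel axis has %d rows; expected %d or %d", d[3], n_ch, n_ch + 8L)
  }
  ld <- dim(labels)
  if (length(ld) != 3L || ld[1] != d[1] || ld[2] != d[2] || ld[3] < 2L) {
    stopf("labels must be subjects x trials x >=2 (valence, arousal first)")
  }
  trials <- list()
  lab <- NULL
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      sid <- sprintf("s%02d", i)
      tid <- sprintf("t%02d", j)
      trials[[length(trials) + 1L]] <-
        eeg_trial(data[i, j, , ], fs = fs, channel_names = channel_names,
                  subject_id = sid, trial_id = tid)
      lab <- rbind(lab, data.frame(subject_id = sid, trial_id = tid,
                                   valence = labels[i, j, 1],
                                   arousal = labels[i, j, 2]))
    }
  }
  recording_set(trials, lab, name = "deap_array", montage_id = "deap32")
}
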