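# Electrode combination: collapse a multichannel trial into per-area means.

#' Combine channels into brain-area averages
#'
#' Replaces the channel dimension by the montage's areas: each output row is
#' the unweighted arithmetic mean, sample by sample, of that area's member
#' channels. Channels declared unassigned in the montage (the midline
#' electrodes of the reference layout) do not contribute to any area. Area
#' order is the montage's area order; the sample count is preserved.
#'
#' @param trial An [eeg_trial] whose channels cover every montage label.
#' @param montage An [eeg_montage]; default [deap_montage()].
#' @return An [eeg_trial] with one "channel" per area; carries attributes
#'   `areas` (the montage area names) and `source_trial`.
#' @export
#' @examples
#' tr <- eeg_trial(matrix(1, 32, 64), 128, deap_channels())
#' combine_areas(tr)$data[, 1]   # all areas 1
combine_areas <- function(trial, montage = deap_montage()) {
  stopifnot(inherits(trial, "eeg_trial"), inherits(montage, "eeg_montage"))
  out <- matrix(0, length(montage$areas), ncol(trial$data))
  for (a in seq_along(montage$areas)) {
    members <- montage$areas[[a]]
    miss <- setdiff(members, trial$channel_names)
    if (length(miss)) {
      stopf("trial %s/%s lacks channel(s) %s required by area %s",
            trial$subject_id, trial$trial_id,
            paste(miss, collapse = ", "), montage$area_names[a])
    }
    rows <- match(members, trial$channel_names)
    out[a, ] <- colMeans(trial$data[rows, , drop = FALSE])
  }
  res <- eeg_trial(out, fs = trial$fs, channel_names = montage$area_names,
                   subject_id = trial$subject_id, trial_id = trial$trial_id)
  attr(res, "areas") <- montage$area_names
  attr(res, "source_trial") <- paste(trial$subject_id, trial$trial_id,
                                     sep = "/")
  res
}
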