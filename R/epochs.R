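#' Epoched EEG trials for one participant
#'
#' The universal data currency of the package: a dense numeric array of
#' `trials x channels x samples` (microvolts) together with its time axis,
#' per-trial behavioural labels and participant metadata.
#'
#' @param data numeric array, trials x channels x samples, in microvolts.
#' @param sfreq sampling frequency in Hz.
#' @param times numeric vector of per-sample times in seconds relative to
#'   stimulus onset; must be strictly increasing and uniformly spaced at
#'   `1/sfreq`.
#' @param trial_labels factor or character vector, one condition label per
#'   trial (`"congruent"` / `"incongruent"`).
#' @param correctness logical vector, one entry per trial.
#' @param rt numeric vector of reaction times in milliseconds, one per trial.
#' @param participant_id single string identifying the participant.
#' @param group_label single string naming the participant's age group.
#' @param channel_names optional character vector of channel names
#'   (10-20 nomenclature); defaults to `ch01`, `ch02`, ...
#'
#' @return An object of class `EpochSet`.
#' @export
epoch_set <- function(data, sfreq, times, trial_labels,
                      correctness = NULL, rt = NULL,
                      participant_id = "p01", group_label = "unknown",
                      channel_names = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  n_trials <- dim(data)[1]
  n_channels <- dim(data)[2]
  n_samples <- dim(data)[3]
  if (length(times) != n_samples)
    stop("`times` length does not match the sample dimension of `data`")
  if (n_samples > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - 1 / sfreq)) > 1e-6 / sfreq)
      stop("`times` must be strictly increasing and uniformly spaced at 1/sfreq")
  }
  trial_labels <- as.factor(trial_labels)
  if (length(trial_labels) != n_trials)
    stop("`trial_labels` length does not match the trial dimension")
  if (is.null(correctness)) correctness <- rep(TRUE, n_trials)
  if (is.null(rt)) rt <- rep(NA_real_, n_trials)
  if (length(correctness) != n_trials || length(rt) != n_trials)
    stop("`correctness` and `rt` must have one entry per trial")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(n_channels))
  structure(
    list(data = data, sfreq = sfreq, times = as.numeric(times),
         trial_labels = trial_labels,
         correctness = as.logical(correctness), rt = as.numeric(rt),
         participant_id = participant_id, group_label = group_label,
         channel_names = channel_names),
    class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<EpochSet> %s (group: %s)\n", x$participant_id, x$group_label))
  cat(sprintf("  %d trials x %d channels x %d samples @ %g Hz, %.1f..%.1f ms\n",
              d[1], d[2], d[3], x$sfreq,
              1000 * x$times[1], 1000 * x$times[length(x$times)]))
  cat("  conditions:", paste(sprintf("%s=%d", levels(x$trial_labels),
                                     tabulate(x$trial_labels)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Number of trials / channels / samples of an EpochSet
#' @param x an `EpochSet`.
#' @return integer count.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(x) dim(x$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(x) dim(x$data)[3]

#' Subset trials of an EpochSet
#'
#' @param x an `EpochSet`.
#' @param idx integer or logical index into trials.
#' @return an `EpochSet` with the selected trials, labels kept in step.
#' @export
subset_trials <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], x$sfreq, x$times,
            droplevels(x$trial_labels[idx]),
            x$correctness[idx], x$rt[idx],
            x$participant_id, x$group_label, x$channel_names)
}

# Stack trials of several participants into one flat bundle used by the
# group decoder: trials array plus per-trial participant/group vectors.
pool_trials <- function(dataset) {
  stopifnot(length(dataset) > 0)
  n_tot <- sum(vapply(dataset, n_trials, 1L))
  nc <- n_channels(dataset[[1]])
  ns <- n_samples(dataset[[1]])
  data <- array(NA_real_, c(n_tot, nc, ns))
  participant <- character(n_tot)
  group <- character(n_tot)
  condition <- character(n_tot)
  at <- 0L
  for (ep in dataset) {
    k <- n_trials(ep)
    if (k == 0L) next
    data[at + seq_len(k), , ] <- ep$data
    participant[at + seq_len(k)] <- ep$participant_id
    group[at + seq_len(k)] <- ep$group_label
    condition[at + seq_len(k)] <- as.character(ep$trial_labels)
    at <- at + k
  }
  list(data = data, participant = participant, group = group,
       condition = condition, sfreq = dataset[[1]]$sfreq,
       times = dataset[[1]]$times)
}
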