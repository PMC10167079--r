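#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed linear-phase FIR design with the usual neurophysiology
#' transition bandwidths (lower: `min(max(low * 0.25, 2), low)` Hz, upper:
#' `min(max(high * 0.25, 2), sfreq/2 - high)` Hz) and filter length
#' `3.3 / transition` seconds rounded up to an odd number of taps. Applied
#' once per channel per trial with group-delay compensation (zero net
#' phase); edges are padded by constant extension. If the designed kernel
#' is longer than the epoch it is truncated to the epoch length with a
#' warning, which degrades the low-frequency edge response.
#'
#' @param epochs an [epoch_set()].
#' @param low,high band edges in Hz, `0 < low < high < sfreq/2`.
#' @return An `EpochSet` with identical dimensions.
#' @export
bandpass <- function(epochs, low, high) {
  sfreq <- epochs$sfreq
  if (!(low > 0 && low < high && high < sfreq / 2))
    stop("band edges must satisfy 0 < low < high < sfreq/2")
  l_trans <- min(max(low * 0.25, 2), low)
  h_trans <- min(max(high * 0.25, 2), sfreq / 2 - high)
  n_taps <- ceiling(3.3 * sfreq / min(l_trans, h_trans))
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  ns <- n_samples(epochs)
  if (n_taps > ns) {
    warning(sprintf(
      "FIR length (%d taps) exceeds epoch length (%d samples); truncating",
      n_taps, ns))
    n_taps <- if (ns %% 2 == 0) ns - 1 else ns
  }
  h <- signal::fir1(n_taps - 1, c(low, high) / (sfreq / 2), type = "pass",
                    window = signal::hamming(n_taps))
  d <- (n_taps - 1) / 2
  out <- epochs
  for (i in seq_len(n_trials(epochs))) {
    for (ch in seq_len(n_channels(epochs))) {
      x <- epochs$data[i, ch, ]
      xp <- c(rep(x[1], d), x, rep(x[ns], d))
      y <- stats::filter(xp, h, method = "convolution", sides = 1)
      out$data[i, ch, ] <- y[(2 * d + 1):(2 * d + ns)]
    }
  }
  out
}

#' FFT-based resampling of epoched data
#'
#' Fourier resampling (spectrum truncation / zero padding): the new sample
#' count is `round(n_samples * target_sfreq / sfreq)` and the time axis is
#' rebuilt from the first original sample at the target rate.
#'
#' @param epochs an [epoch_set()].
#' @param target_sfreq target sampling frequency in Hz, `<= sfreq`.
#' @return A resampled `EpochSet`.
#' @export
resample_epochs <- function(epochs, target_sfreq) {
  if (target_sfreq <= 0) stop("`target_sfreq` must be > 0")
  if (target_sfreq > epochs$sfreq)
    stop("`target_sfreq` must not exceed the current sampling rate")
  if (target_sfreq == epochs$sfreq) return(epochs)
  n <- n_samples(epochs)
  n_new <- as.integer(round(n * target_sfreq / epochs$sfreq))
  data <- array(0, c(n_trials(epochs), n_channels(epochs), n_new))
  for (i in seq_len(n_trials(epochs)))
    for (ch in seq_len(n_channels(epochs)))
      data[i, ch, ] <- fft_resample(epochs$data[i, ch, ], n_new)
  times <- epochs$times[1] + seq(0, n_new - 1) / target_sfreq
  epoch_set(data, target_sfreq, times, epochs$trial_labels,
            epochs$correctness, epochs$rt, epochs$participant_id,
            epochs$group_label, epochs$channel_names)
}

# Fourier-domain resampling of one real signal to n_new samples.
fft_resample <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = rep(0, n_new), imaginary = rep(0, n_new))
  k <- min(n, n_new)
  half <- floor((k + 1) / 2) # positive-frequency bins incl. DC
  Y[seq_len(half)] <- X[seq_len(half)]
  nneg <- k - half
  if (nneg > 0)
    Y[n_new - seq_len(nneg) + 1] <- X[n - seq_len(nneg) + 1]
  if (k %% 2 == 0 && k < max(n, n_new)) {
    # split the shared Nyquist bin symmetrically when downsampling
    if (n_new < n) {
      ny <- (X[half + 1] + X[n - half + 1]) / 2
      Y[half + 1] <- ny
    } else {
      Y[half + 1] <- X[half + 1] / 2
      Y[n_new - half + 1] <- X[half + 1] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Crop epochs to a time window
#'
#' Keeps samples on the existing grid: the lower edge snaps outward to the
#' previous grid sample and the upper edge keeps samples with `t <= end`.
#' At 256 Hz a (-100, 800) ms window therefore yields exactly 231 samples
#' (-101.56 .. 796.88 ms).
#'
#' @param epochs an [epoch_set()].
#' @param start,end window edges in ms.
#' @return A cropped `EpochSet`.
#' @export
crop_epochs <- function(epochs, start, end) {
  fs <- epochs$sfreq
  lo <- floor(start / 1000 * fs + 1e-9) / fs
  keep <- which(epochs$times >= lo - 1e-9 & epochs$times <= end / 1000 + 1e-9)
  if (length(keep) == 0) stop("empty crop window")
  epoch_set(epochs$data[, , keep, drop = FALSE], fs, epochs$times[keep],
            epochs$trial_labels, epochs$correctness, epochs$rt,
            epochs$participant_id, epochs$group_label, epochs$channel_names)
}

#' Keep analysable trials
#'
#' Retains trials with a correct response between 100 ms and 1200 ms after
#' stimulus onset (bounds inclusive) and drops any condition other than
#' congruent / incongruent (e.g. neutral flankers).
#'
#' @param epochs an [epoch_set()].
#' @return An `EpochSet`, possibly with zero trials.
#' @export
select_correct_trials <- function(epochs) {
  keep <- epochs$correctness &
    !is.na(epochs$rt) & epochs$rt >= 100 & epochs$rt <= 1200 &
    as.character(epochs$trial_labels) %in% c("congruent", "incongruent")
  subset_trials(epochs, which(keep))
}

#' Exclude participants with too few correct trials
#'
#' Removes every participant with fewer than `min_trials` correct trials in
#' either condition (strictly less than), and reports per-participant
#' quality control.
#'
#' @param dataset list of correctness-filtered [epoch_set()] objects.
#' @param min_trials exclusion threshold (default 35).
#' @return list with elements `dataset` (retained participants) and
#'   `qc` (data.frame: participant_id, group_label, n_congruent,
#'   n_incongruent, excluded, exclusion_reason).
#' @export
apply_min_trial_filter <- function(dataset, min_trials = 35) {
  if (length(dataset) == 0)
    return(list(dataset = list(), qc = data.frame(
      participant_id = character(), group_label = character(),
      n_congruent = integer(), n_incongruent = integer(),
      excluded = logical(), exclusion_reason = character())))
  qc <- do.call(rbind, lapply(dataset, function(ep) {
    lab <- as.character(ep$trial_labels)
    nc <- sum(lab == "congruent")
    ni <- sum(lab == "incongruent")
    excl <- nc < min_trials || ni < min_trials
    data.frame(participant_id = ep$participant_id,
               group_label = ep$group_label,
               n_congruent = nc, n_incongruent = ni, excluded = excl,
               exclusion_reason = if (excl) "min_trials" else "none",
               stringsAsFactors = FALSE)
  }))
  list(dataset = dataset[!qc$excluded], qc = qc)
}
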