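#' Parametric description of one ERP component
#'
#' An ERP component is modelled as a Gaussian temporal envelope with a fixed
#' spatial topography: `amplitude * exp(-(t - peak_latency)^2 / (2 width^2))`
#' projected onto the channel array through a unit-norm weight vector.
#' Condition deltas are added on incongruent trials only, which is what makes
#' the stimulus type decodable.
#'
#' @param name component label, e.g. `"P1"`, `"N1"`, `"N2"`, `"P3"`.
#' @param peak_latency peak time in ms after stimulus onset.
#' @param latency_sd between-participant latency jitter (ms, sd of a normal).
#' @param amplitude signed peak amplitude in microvolts.
#' @param amplitude_sd between-participant amplitude jitter (microvolts).
#' @param width Gaussian temporal envelope sigma in ms; must be > 0.
#' @param topography per-channel weight vector; normalised to unit Euclidean
#'   norm on construction.
#' @param condition_delta_amplitude microvolts added to the amplitude on
#'   incongruent trials.
#' @param condition_delta_latency ms added to the latency on incongruent
#'   trials.
#' @return A `component_spec` list.
#' @export
component_spec <- function(name, peak_latency, amplitude, topography,
                           width = 30, latency_sd = 0, amplitude_sd = 0,
                           condition_delta_amplitude = 0,
                           condition_delta_latency = 0) {
  if (width <= 0) stop("`width` must be > 0")
  nrm <- sqrt(sum(topography^2))
  if (nrm == 0) stop("`topography` must be non-zero")
  structure(
    list(name = name, peak_latency = peak_latency, latency_sd = latency_sd,
         amplitude = amplitude, amplitude_sd = amplitude_sd, width = width,
         topography = topography / nrm,
         condition_delta_amplitude = condition_delta_amplitude,
         condition_delta_latency = condition_delta_latency),
    class = "component_spec")
}

#' Parametric description of one age group
#'
#' @param name group label (e.g. `"children"`, `"young"`, `"old<75"`).
#' @param n_participants number of simulated participants; must be > 0.
#' @param trial_counts named list with entries `congruent` and `incongruent`,
#'   each a numeric vector `c(mean, sd, min, max)` describing the truncated
#'   normal from which per-participant trial counts are drawn.
#' @param component_overrides named list mapping a component name to
#'   `c(latency_offset_ms, amplitude_scale)`; applied on top of the
#'   component defaults for this group.
#' @param rt_mean named numeric vector `c(congruent=, incongruent=)` of mean
#'   reaction times (ms) for this group.
#' @return A `group_spec` list.
#' @export
group_spec <- function(name, n_participants, trial_counts,
                       component_overrides = list(),
                       rt_mean = c(congruent = 450, incongruent = 500)) {
  if (n_participants <= 0) stop("`n_participants` must be > 0")
  for (cond in c("congruent", "incongruent")) {
    tc <- trial_counts[[cond]]
    if (is.null(tc) || length(tc) != 4)
      stop("`trial_counts$", cond, "` must be c(mean, sd, min, max)")
    if (!(tc[3] <= tc[1] && tc[1] <= tc[4]))
      stop("trial counts must satisfy min <= mean <= max")
  }
  structure(
    list(name = name, n_participants = as.integer(n_participants),
         trial_counts = trial_counts,
         component_overrides = component_overrides, rt_mean = rt_mean),
    class = "group_spec")
}

#' Full simulation configuration
#'
#' @param groups list of [group_spec()] objects.
#' @param components list of [component_spec()] objects.
#' @param sfreq sampling frequency in Hz.
#' @param n_channels number of channels; topographies must match.
#' @param epoch_window `c(start_ms, end_ms)` with start < 0 < end.
#' @param noise_sd per-channel noise standard deviation in microvolts.
#' @param noise_exponent spectral slope of the 1/f background noise.
#' @param snr_scale multiplies all component amplitudes (0 = pure noise).
#' @param seed master seed; all participant seeds derive from it.
#' @param rt_sd reaction-time lognormal sd in ms.
#' @param error_rate named vector `c(congruent=, incongruent=)` of response
#'   error probabilities, each in `[0, 1)`.
#' @param channel_names channel names; defaults to the BioSemi 32 10-20 set
#'   when `n_channels == 32`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(groups, components, sfreq = 256, n_channels = 32,
                       epoch_window = c(-100, 800), noise_sd = 5,
                       noise_exponent = 1, snr_scale = 1, seed = 1L,
                       rt_sd = 90,
                       error_rate = c(congruent = 0.04, incongruent = 0.08),
                       channel_names = NULL) {
  if (sfreq <= 0) stop("`sfreq` must be > 0")
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0))
    stop("`epoch_window` must straddle stimulus onset (start < 0 < end)")
  if (any(error_rate < 0 | error_rate >= 1))
    stop("`error_rate` must be in [0, 1)")
  for (comp in components) {
    if (length(comp$topography) != n_channels)
      stop("topography of component '", comp$name,
           "' does not match `n_channels`")
    if (comp$peak_latency < epoch_window[1] ||
        comp$peak_latency > epoch_window[2])
      stop("peak latency of component '", comp$name,
           "' lies outside the epoch window")
  }
  if (is.null(channel_names)) {
    channel_names <- if (n_channels == 32) biosemi32_layout()$name
      else sprintf("ch%02d", seq_len(n_channels))
  }
  structure(
    list(groups = groups, components = components, sfreq = sfreq,
         n_channels = as.integer(n_channels), epoch_window = epoch_window,
         noise_sd = noise_sd, noise_exponent = noise_exponent,
         snr_scale = snr_scale, seed = as.integer(seed), rt_sd = rt_sd,
         error_rate = error_rate, channel_names = channel_names),
    class = "sim_config")
}

#' Approximate 2-d layout of the BioSemi 32-channel 10-20 montage
#'
#' Flattened head coordinates (x = left-right, y = posterior-negative) used
#' to build smooth spatial topographies.
#'
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
biosemi32_layout <- function() {
  data.frame(
    name = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
             "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
             "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
             "PO3", "PO4", "O1", "Oz", "O2"),
    x = c(-0.30, 0.30, -0.35, 0.35, -0.80, -0.45, 0, 0.45, 0.80,
          -0.65, -0.25, 0.25, 0.65, -0.95, -0.50, 0, 0.50, 0.95,
          -0.65, -0.25, 0.25, 0.65, -0.80, -0.45, 0, 0.45, 0.80,
          -0.35, 0.35, -0.30, 0, 0.30),
    y = c(0.95, 0.95, 0.80, 0.80, 0.55, 0.55, 0.55, 0.55, 0.55,
          0.30, 0.30, 0.30, 0.30, 0, 0, 0, 0, 0,
          -0.30, -0.30, -0.30, -0.30, -0.55, -0.55, -0.55, -0.55, -0.55,
          -0.80, -0.80, -0.95, -0.95, -0.95))
}

#' Smooth Gaussian topography over a 2-d channel layout
#'
#' @param center `c(x, y)` of the spatial peak in layout coordinates.
#' @param sigma spatial spread in layout units.
#' @param layout data.frame with `x`, `y` columns; defaults to
#'   [biosemi32_layout()].
#' @return unit-norm numeric weight vector, one entry per channel.
#' @export
gaussian_topography <- function(center, sigma = 0.5,
                                layout = biosemi32_layout()) {
  d2 <- (layout$x - center[1])^2 + (layout$y - center[2])^2
  w <- exp(-d2 / (2 * sigma^2))
  w / sqrt(sum(w^2))
}

#' Default simulation configuration emulating the lifespan flanker study
#'
#' Six age groups with the study's group sizes and per-condition correct
#' trial-count distributions; P1/N1 (occipital), N2 (fronto-central) and P3
#' (parietal) components; children and the two oldest groups carry slower,
#' larger early components (the u-shaped latency pattern) and a +150 ms
#' shift of the condition-discriminative N2/P3 window; the incongruent
#' condition gets a larger (more negative) N2 and a delayed P3.
#'
#' @param seed master seed.
#' @param ... overrides passed on to [sim_config()] (e.g. `noise_sd`,
#'   `snr_scale`, `sfreq`).
#' @return A `sim_config`.
#' @export
make_default_config <- function(seed = 1L, ...) {
  tc <- function(m, s, lo, hi) c(m, s, lo, hi)
  slow_early <- list(P1 = c(80, 1.4), N1 = c(80, 1.4),
                     N2 = c(150, 1.0), P3 = c(150, 1.0))
  groups <- list(
    group_spec("children", 46,
               list(congruent = tc(65.78, 13.27, 38, 94),
                    incongruent = tc(70.91, 15.30, 36, 98)),
               component_overrides = slow_early,
               rt_mean = c(congruent = 640, incongruent = 700)),
    group_spec("young", 39,
               list(congruent = tc(63.49, 22.59, 36, 109),
                    incongruent = tc(65.49, 24.31, 40, 109)),
               rt_mean = c(congruent = 420, incongruent = 460)),
    group_spec("early-ma", 21,
               list(congruent = tc(92.90, 8.39, 75, 106),
                    incongruent = tc(97.05, 10.33, 79, 125)),
               rt_mean = c(congruent = 450, incongruent = 490)),
    group_spec("late-ma", 25,
               list(congruent = tc(94.88, 9.01, 80, 113),
                    incongruent = tc(95.12, 10.65, 71, 109)),
               rt_mean = c(congruent = 480, incongruent = 525)),
    group_spec("old<75", 40,
               list(congruent = tc(56.58, 14.42, 41, 92),
                    incongruent = tc(58.88, 19.73, 40, 111)),
               component_overrides = slow_early,
               rt_mean = c(congruent = 530, incongruent = 580)),
    group_spec("veryold>75", 38,
               list(congruent = tc(65.95, 21.60, 36, 101),
                    incongruent = tc(69.26, 21.07, 39, 105)),
               component_overrides = slow_early,
               rt_mean = c(congruent = 560, incongruent = 615)))
  components <- list(
    component_spec("P1", peak_latency = 100, amplitude = 5,
                   topography = gaussian_topography(c(0.15, -0.95), 0.40),
                   width = 25, latency_sd = 10, amplitude_sd = 1),
    component_spec("N1", peak_latency = 170, amplitude = -5,
                   topography = gaussian_topography(c(0.00, -0.90), 0.45),
                   width = 30, latency_sd = 12, amplitude_sd = 1),
    component_spec("N2", peak_latency = 250, amplitude = -4,
                   topography = gaussian_topography(c(0.00, 0.35), 0.50),
                   width = 40, latency_sd = 15, amplitude_sd = 1,
                   condition_delta_amplitude = -2),
    component_spec("P3", peak_latency = 400, amplitude = 6,
                   topography = gaussian_topography(c(0.00, -0.55), 0.60),
                   width = 80, latency_sd = 25, amplitude_sd = 1.5,
                   condition_delta_latency = 40))
  sim_config(groups = groups, components = components, seed = seed, ...)
}

#' Coloured (1/f^exponent) Gaussian noise
#'
#' Generates zero-mean noise whose power spectral density follows
#' `1/f^exponent`, independently per channel, rescaled so that every
#' channel has exactly the requested standard deviation.
#'
#' @param n_channels number of channels.
#' @param n_samples number of samples; must be > 1.
#' @param sfreq sampling frequency in Hz (sets the frequency axis only).
#' @param exponent spectral slope; `0` gives white noise. Must be >= 0.
#' @param sd target per-channel standard deviation (microvolts); `0` yields
#'   an all-zero matrix.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return numeric matrix, channels x samples.
#' @export
make_noise <- function(n_channels, n_samples, sfreq, exponent = 1, sd = 1,
                       seed = NULL) {
  if (n_samples <= 1) stop("`n_samples` must be > 1")
  if (exponent < 0) stop("`exponent` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0, n_channels, n_samples)
  if (sd == 0) return(out)
  freqs <- seq(0, n_samples - 1) * sfreq / n_samples
  # two-sided frequency magnitudes; DC removed for zero mean
  f2 <- pmin(freqs, sfreq - freqs)
  gain <- c(0, f2[-1]^(-exponent / 2))
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(n_samples)
    x <- Re(stats::fft(stats::fft(w) * gain, inverse = TRUE)) / n_samples
    x <- x - mean(x)
    out[ch, ] <- x * sd / stats::sd(x)
  }
  out
}

# Sample times of an epoch window (ms) on the sampling grid: the lower edge
# snaps outward to the previous grid sample, the upper edge keeps samples up
# to `end` (floor). At 256 Hz, (-100, 800) -> samples -26..204, 231 samples.
epoch_sample_range <- function(window_ms, sfreq) {
  k0 <- floor(window_ms[1] / 1000 * sfreq + 1e-9)
  k1 <- floor(window_ms[2] / 1000 * sfreq + 1e-9)
  seq.int(k0, k1)
}

# truncated-normal integer draw via rejection with a clamping fallback
draw_trial_count <- function(tc) {
  for (i in 1:200) {
    k <- round(stats::rnorm(1, tc[1], tc[2]))
    if (k >= tc[3] && k <= tc[4]) return(as.integer(k))
  }
  as.integer(min(max(round(tc[1]), tc[3]), tc[4]))
}

#' Simulate one participant's epoched EEG
#'
#' Each trial is the sum over components of
#' `amplitude * exp(-(t - latency)^2 / (2 width^2)) * topography`
#' plus 1/f noise. Latency and amplitude are drawn once per participant
#' (between-participant variability); condition deltas are added on
#' incongruent trials; `snr_scale` multiplies all component amplitudes.
#' Trial counts per condition come from the group's truncated normal;
#' reaction times are lognormal and correctness is Bernoulli per condition.
#'
#' @param config a [sim_config()].
#' @param group a [group_spec()]; usually one of `config$groups`.
#' @param seed participant seed (integer).
#' @return An [epoch_set()].
#' @export
simulate_participant <- function(config, group, seed) {
  set.seed(seed)
  n_cong <- draw_trial_count(group$trial_counts$congruent)
  n_inc <- draw_trial_count(group$trial_counts$incongruent)
  if (n_cong + n_inc <= 0) stop("non-positive trial count after truncation")
  kk <- epoch_sample_range(config$epoch_window, config$sfreq)
  times <- kk / config$sfreq
  ns <- length(times)
  nc <- config$n_channels
  t_ms <- times * 1000

  # participant-level component draws, then per-condition evoked responses
  evoked <- list(congruent = matrix(0, nc, ns),
                 incongruent = matrix(0, nc, ns))
  for (comp in config$components) {
    ov <- group$component_overrides[[comp$name]] %||% c(0, 1)
    lat_p <- comp$peak_latency + ov[1] + stats::rnorm(1, 0, comp$latency_sd)
    amp_p <- comp$amplitude * ov[2] + stats::rnorm(1, 0, comp$amplitude_sd)
    for (cond in c("congruent", "incongruent")) {
      lat <- lat_p + if (cond == "incongruent") comp$condition_delta_latency else 0
      amp <- amp_p + if (cond == "incongruent") comp$condition_delta_amplitude else 0
      env <- exp(-(t_ms - lat)^2 / (2 * comp$width^2))
      evoked[[cond]] <- evoked[[cond]] +
        config$snr_scale * amp * comp$topography %o% env
    }
  }

  conds <- sample(c(rep("congruent", n_cong), rep("incongruent", n_inc)))
  n_tot <- length(conds)
  data <- array(0, c(n_tot, nc, ns))
  for (i in seq_len(n_tot)) {
    data[i, , ] <- evoked[[conds[i]]] +
      make_noise(nc, ns, config$sfreq, config$noise_exponent,
                 config$noise_sd)
  }

  rt_m <- group$rt_mean[conds]
  # lognormal parametrised by arithmetic mean / sd
  cv2 <- (config$rt_sd / rt_m)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(rt_m) - sdlog^2 / 2
  rt <- stats::rlnorm(n_tot, meanlog, sdlog)
  correct <- stats::runif(n_tot) >= config$error_rate[conds]

  epoch_set(data, config$sfreq, times, factor(conds),
            correctness = correct, rt = rt,
            participant_id = sprintf("%s_s%d", group$name, seed),
            group_label = group$name, channel_names = config$channel_names)
}

#' Simulate a full multi-group dataset
#'
#' One [epoch_set()] per participant per group; participant seeds are
#' derived deterministically from `config$seed`, so identical configs give
#' identical datasets.
#'
#' @param config a [sim_config()].
#' @return list of `EpochSet`, in group order.
#' @export
simulate_dataset <- function(config) {
  out <- list()
  for (g in seq_along(config$groups)) {
    grp <- config$groups[[g]]
    for (p in seq_len(grp$n_participants)) {
      ep <- simulate_participant(config, grp, derive_seed(config$seed, g, p))
      ep$participant_id <- sprintf("%s_p%02d", grp$name, p)
      out[[length(out) + 1L]] <- ep
    }
  }
  out
}
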