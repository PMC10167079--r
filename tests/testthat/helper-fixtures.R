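# Shared fixtures: all synthetic, generated at test time.

layout16 <- erpdecode::biosemi32_layout()[seq(1, 32, by = 2), ]

topo16 <- function(center, sigma = 0.5)
  erpdecode::gaussian_topography(center, sigma, layout16)

# Single-component, noise-free configuration with latencies on the sample
# grid: every quantity has a closed form.
noisefree_config <- function(amp = 5, delta_amp = 0, seed = 1L) {
  groups <- list(group_spec("solo", 2,
                            list(congruent = c(10, 0, 10, 10),
                                 incongruent = c(10, 0, 10, 10))))
  comps <- list(component_spec(
    "P1", peak_latency = 125, amplitude = amp,         # 125 ms on 64 Hz grid
    topography = topo16(c(0.15, -0.95), 0.4), width = 25,
    condition_delta_amplitude = delta_amp))
  sim_config(groups, comps, sfreq = 64, n_channels = 16, noise_sd = 0,
             noise_exponent = 0, seed = seed, error_rate = c(congruent = 0,
                                                             incongruent = 0),
             channel_names = layout16$name)
}

# Two clearly different groups (distinct N2 latency/topography) at 64 Hz;
# used for group-decoding tests.
twogroup_config <- function(n_per_group = 4, n_trials = 30, noise_sd = 3,
                            snr_scale = 1, seed = 1L, jitter = TRUE) {
  tc <- c(n_trials / 2, 0, n_trials / 2, n_trials / 2)
  groups <- list(
    group_spec("young", n_per_group,
               list(congruent = tc, incongruent = tc)),
    group_spec("old<75", n_per_group,
               list(congruent = tc, incongruent = tc),
               component_overrides = list(N2 = c(150, 1.6),
                                          P3 = c(100, 0.6))))
  comps <- list(
    component_spec("N2", peak_latency = 250, amplitude = -4,
                   topography = topo16(c(0, 0.35), 0.5), width = 40,
                   latency_sd = if (jitter) 8 else 0,
                   amplitude_sd = if (jitter) 0.5 else 0),
    component_spec("P3", peak_latency = 400, amplitude = 6,
                   topography = topo16(c(0, -0.55), 0.6), width = 80,
                   latency_sd = if (jitter) 10 else 0,
                   amplitude_sd = if (jitter) 0.5 else 0))
  sim_config(groups, comps, sfreq = 64, n_channels = 16,
             noise_sd = noise_sd, snr_scale = snr_scale, seed = seed,
             error_rate = c(congruent = 0, incongruent = 0),
             channel_names = layout16$name)
}

# One participant with a condition effect (incongruent N2 larger) on top of
# pink noise; used for stimulus-decoding tests.
condition_effect_participant <- function(n_per_cond = 50, delta = -3,
                                         effect_latency = 250,
                                         noise_sd = 3, seed = 7L) {
  tc <- c(n_per_cond, 0, n_per_cond, n_per_cond)
  grp <- group_spec("solo", 1, list(congruent = tc, incongruent = tc))
  comps <- list(
    component_spec("P1", peak_latency = 125, amplitude = 5,
                   topography = topo16(c(0.15, -0.95), 0.4), width = 25),
    component_spec("COND", peak_latency = effect_latency, amplitude = 0,
                   topography = topo16(c(0, 0.35), 0.5), width = 40,
                   condition_delta_amplitude = delta))
  cfg <- sim_config(list(grp), comps, sfreq = 64, n_channels = 16,
                    noise_sd = noise_sd, seed = seed,
                    error_rate = c(congruent = 0, incongruent = 0),
                    channel_names = layout16$name)
  simulate_participant(cfg, grp, seed = seed)
}

# Bare-bones stand-in EpochSets (id + group only) for CV geometry tests.
dummy_dataset <- function(group_sizes) {
  out <- list()
  for (g in seq_along(group_sizes)) {
    for (p in seq_len(group_sizes[g])) {
      out[[length(out) + 1L]] <- structure(
        list(participant_id = sprintf("g%d_p%02d", g, p),
             group_label = names(group_sizes)[g] %||% paste0("g", g)),
        class = "EpochSet")
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-channel EpochSet wrapping a signal matrix (trials x samples).
signal_epochs <- function(x, sfreq, t0 = 0) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  data <- array(x, c(nrow(x), 1, ncol(x)))
  epoch_set(data, sfreq, t0 + seq(0, ncol(x) - 1) / sfreq,
            rep("congruent", nrow(x)))
}
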