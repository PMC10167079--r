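#' Assemble and validate a full-pipeline run configuration
#'
#' One document holding every stage's parameters. Unknown keys and
#' out-of-range values are rejected.
#'
#' @param sim a [sim_config()].
#' @param min_trials participant exclusion threshold (correct trials per
#'   condition).
#' @param bandpass `c(low, high)` in Hz, or `NULL` to skip filtering.
#' @param target_sfreq resample target in Hz, or `NULL` to keep the
#'   simulated rate.
#' @param crop `c(start_ms, end_ms)`, or `NULL` to keep the full epoch.
#' @param window a [window_spec()].
#' @param n_components xDAWN components per class.
#' @param n_folds folds (group decoding) and splits (stimulus decoding).
#' @param test_fraction within-participant held-out fraction.
#' @param n_permutations label permutations per participant.
#' @param alpha significance level.
#' @param seed master seed for cross-validation, subsampling and
#'   permutations (the simulation uses `sim$seed`).
#' @param group_time_resolved also run sliding-window group decoding.
#' @return A validated `run_config` list.
#' @export
run_config <- function(sim, min_trials = 35, bandpass = NULL,
                       target_sfreq = NULL, crop = NULL,
                       window = window_spec(), n_components = 5,
                       n_folds = 10, test_fraction = 0.20,
                       n_permutations = 1000, alpha = 0.05, seed = 1L,
                       group_time_resolved = FALSE) {
  stopifnot(inherits(sim, "sim_config"), inherits(window, "window_spec"))
  if (min_trials < 0) stop("`min_trials` must be >= 0")
  if (!is.null(bandpass) &&
      !(length(bandpass) == 2 && bandpass[1] > 0 && bandpass[1] < bandpass[2]))
    stop("`bandpass` must be c(low, high) with 0 < low < high")
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("`test_fraction` must be in (0, 1)")
  structure(list(sim = sim, min_trials = min_trials, bandpass = bandpass,
                 target_sfreq = target_sfreq, crop = crop, window = window,
                 n_components = n_components, n_folds = n_folds,
                 test_fraction = test_fraction,
                 n_permutations = n_permutations, alpha = alpha,
                 seed = as.integer(seed),
                 group_time_resolved = group_time_resolved),
            class = "run_config")
}

#' A small smoke-test configuration
#'
#' Two groups x four participants, ~40 trials per participant, 20
#' permutations: every pipeline stage runs in seconds.
#'
#' @param seed master seed.
#' @return A `run_config`.
#' @export
smoke_run_config <- function(seed = 1L) {
  layout16 <- biosemi32_layout()[seq(1, 32, by = 2), ]
  topo <- function(center, sigma) gaussian_topography(center, sigma, layout16)
  groups <- list(
    group_spec("young", 4, list(congruent = c(20, 3, 12, 30),
                                incongruent = c(20, 3, 12, 30))),
    group_spec("old<75", 4, list(congruent = c(20, 3, 12, 30),
                                 incongruent = c(20, 3, 12, 30)),
               component_overrides = list(N2 = c(120, 1.3))))
  components <- list(
    component_spec("N2", peak_latency = 250, amplitude = -4,
                   topography = topo(c(0, 0.35), 0.5), width = 40,
                   condition_delta_amplitude = -2.5),
    component_spec("P3", peak_latency = 400, amplitude = 6,
                   topography = topo(c(0, -0.55), 0.6), width = 80))
  sim <- sim_config(groups, components, sfreq = 64, n_channels = 16,
                    noise_sd = 3, seed = seed,
                    channel_names = layout16$name)
  run_config(sim, min_trials = 5, window = window_spec(10, 5),
             n_components = 2, n_folds = 4, n_permutations = 20,
             seed = seed)
}

#' Run the full decoding pipeline
#'
#' simulate -> quality control -> optional filter/resample/crop -> group
#' decoding (whole trial, binomial threshold) -> within-participant
#' stimulus decoding (trajectories, permutation null, group threshold,
#' peak metrics) -> between-group statistics on peak score and peak time.
#' All artifacts are written to `out_dir` when given; identical configs
#' produce identical results.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param verbose print stage progress.
#' @return list with `qc`, `dataset` summary, `group_confusion`,
#'   `binomial`, `group_trajectory` (optional), `trajectories`,
#'   `null_samples`, `perm_threshold`, `peaks`, `stats_max_score`,
#'   `stats_peak_time`.
#' @export
run_full_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("stage simulate")
  dataset <- stage("simulate", simulate_dataset(config$sim))

  say("stage prep")
  prep_res <- stage("prep", {
    ds <- lapply(dataset, select_correct_trials)
    if (!is.null(config$bandpass))
      ds <- lapply(ds, bandpass, low = config$bandpass[1],
                   high = config$bandpass[2])
    if (!is.null(config$target_sfreq))
      ds <- lapply(ds, resample_epochs, target_sfreq = config$target_sfreq)
    if (!is.null(config$crop))
      ds <- lapply(ds, crop_epochs, start = config$crop[1],
                   end = config$crop[2])
    apply_min_trial_filter(ds, config$min_trials)
  })
  ds <- prep_res$dataset
  if (length(ds) == 0)
    stop("pipeline stage 'prep' failed: every participant excluded by QC",
         call. = FALSE)
  groups <- vapply(ds, function(e) e$group_label, "")
  n_groups <- length(unique(groups))

  say("stage decode-group (%d participants, %d groups)", length(ds), n_groups)
  plan_b <- cv_plan("between_participants", n_folds = config$n_folds,
                    seed = derive_seed(config$seed, 10L))
  group_confusion <- stage("decode-group",
    decode_whole_trial(ds, plan_b, config$n_components))
  binom <- list(
    threshold = binomial_threshold(group_confusion$n, n_groups,
                                   config$alpha),
    alpha = config$alpha, method = "binomial", n = group_confusion$n,
    n_classes = n_groups)
  group_traj <- NULL
  if (isTRUE(config$group_time_resolved))
    group_traj <- stage("decode-group-time",
      decode_time_resolved(ds, plan_b, config$window, config$n_components,
                           metric = "accuracy"))

  say("stage decode-task + permutations")
  trajectories <- list()
  null_samples <- list()
  for (i in seq_along(ds)) {
    ep <- ds[[i]]
    plan_w <- cv_plan("within_participant", n_folds = config$n_folds,
                      test_fraction = config$test_fraction,
                      seed = derive_seed(config$seed, 11L, i))
    trajectories[[ep$participant_id]] <- stage("decode-task",
      decode_time_resolved(ep, plan_w, config$window, config$n_components,
                           metric = "auc"))
    null_samples[[ep$participant_id]] <- stage("permutation",
      permutation_null(ep, config$n_permutations,
                       seed = derive_seed(config$seed, 12L, i),
                       plan = plan_w, window = config$window,
                       n_components = config$n_components))
  }
  perm_thr <- group_threshold(null_samples, config$alpha)

  say("stage stats")
  peaks <- do.call(rbind, lapply(seq_along(ds), function(i)
    extract_peak(trajectories[[i]], perm_thr$threshold,
                 ds[[i]]$participant_id, ds[[i]]$group_label)))
  stats_max <- stage("stats",
    omnibus_and_posthoc(split(peaks$max_score, peaks$group_label),
                        alpha = config$alpha))
  stats_time <- stage("stats",
    omnibus_and_posthoc(split(peaks$peak_time, peaks$group_label),
                        alpha = config$alpha))

  result <- list(qc = prep_res$qc,
                 n_participants = length(ds),
                 group_confusion = group_confusion, binomial = binom,
                 group_trajectory = group_traj,
                 trajectories = trajectories, null_samples = null_samples,
                 perm_threshold = perm_thr, peaks = peaks,
                 stats_max_score = stats_max, stats_peak_time = stats_time)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, config, out_dir)
  result
}

format_num <- function(x) signif(x, 12)

write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$qc, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$peaks, file.path(out_dir, "peak_metrics.csv"),
                   row.names = FALSE)
  traj <- do.call(rbind, lapply(names(result$trajectories), function(id) {
    tr <- result$trajectories[[id]]
    data.frame(participant = id,
               window_center_s = format_num(tr$window_centers),
               metric = tr$metric,
               score = format_num(tr$mean_curve),
               ci95 = format_num(tr$ci95))
  }))
  utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                   row.names = FALSE)
  cm <- result$group_confusion
  jsonlite::write_json(
    list(matrix = unclass(as.matrix(cm$matrix)),
         classes = rownames(cm$matrix),
         precision = cm$precision, recall = cm$recall,
         accuracy = cm$accuracy, n = cm$n),
    file.path(out_dir, "confusion.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(binomial = result$binomial,
         permutation = list(threshold = result$perm_threshold$threshold,
                            alpha = result$perm_threshold$alpha,
                            n_null = result$perm_threshold$n_permutations)),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)
  stats_obj <- lapply(
    list(max_score = result$stats_max_score,
         peak_time = result$stats_peak_time),
    function(s) list(omnibus = s$omnibus, posthoc = s$posthoc,
                     route = s$normality_gate$route))
  jsonlite::write_json(stats_obj, file.path(out_dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "erpdecode",
                   version = as.character(utils::packageVersion("erpdecode")),
                   seed = config$seed, sim_seed = config$sim$seed,
                   n_permutations = config$n_permutations,
                   alpha = config$alpha,
                   window = unclass(config$window),
                   n_components = config$n_components,
                   n_folds = config$n_folds)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
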