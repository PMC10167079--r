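#' Binomial chance-level threshold for classification accuracy
#'
#' The analytic significance threshold of a classifier (Combrisson & Jerbi
#' style): the smallest integer `k*` whose cumulative
#' `Binomial(n_trials, 1/n_classes)` probability reaches `1 - alpha`,
#' divided by `n_trials`. Accuracies strictly above the threshold are
#' declared significant.
#'
#' @param n_trials number of classified trials (>= 1).
#' @param n_classes number of classes (>= 2).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return accuracy threshold in `[1/n_classes, 1]`.
#' @export
binomial_threshold <- function(n_trials, n_classes, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  if (n_trials < 1 || n_classes < 2)
    stop("need `n_trials` >= 1 and `n_classes` >= 2")
  stats::qbinom(1 - alpha, n_trials, 1 / n_classes) / n_trials
}

#' Label-permutation null distribution of a decoding statistic
#'
#' Re-runs the full within-participant decoding pipeline (stratified
#' splits, xDAWN, sliding-window SVM, fold-mean AUC) with condition labels
#' shuffled across trials, and records the null statistic — by default the
#' maximum over time windows of the fold-mean AUC, matching how peak
#' performance is compared against the threshold. Shuffling happens before
#' splitting, and each permutation uses independent split seeds.
#'
#' @param epochs an [epoch_set()] with two conditions.
#' @param n_permutations number of label shuffles (>= 1; the study design
#'   uses 1000, calibration suites run 100-200).
#' @param seed integer seed for shuffles and split streams.
#' @param plan a within-participant [cv_plan()]; its seed is re-derived per
#'   permutation.
#' @param window,n_components,cost,gamma decoding settings, as in
#'   [decode_time_resolved()].
#' @param decode_fn optional override: `function(epochs, labels, seed)`
#'   returning a `DecodeTrajectory`; the null statistic is
#'   `statistic(trajectory)`.
#' @param statistic function mapping a trajectory to the scalar null
#'   statistic (default `max(mean_curve)`).
#' @return numeric vector of `n_permutations` null statistics.
#' @export
permutation_null <- function(epochs, n_permutations = 1000, seed = 1L,
                             plan = cv_plan("within_participant"),
                             window = window_spec(), n_components = 5,
                             cost = 1, gamma = NULL, decode_fn = NULL,
                             statistic = function(tr) max(tr$mean_curve)) {
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  labels <- factor(epochs$trial_labels)
  if (nlevels(labels) < 2) stop("labels contain a single class")
  if (is.null(decode_fn)) {
    decode_fn <- function(ep, lab, s) {
      p <- plan; p$seed <- s
      decode_time_resolved(ep, p, window, n_components, metric = "auc",
                           labels = lab, cost = cost, gamma = gamma)
    }
  }
  vapply(seq_len(n_permutations), function(p) {
    perm <- with_seed(derive_seed(seed, 5L, p), sample(labels))
    statistic(decode_fn(epochs, perm, derive_seed(seed, 6L, p)))
  }, 1.0)
}

#' Group-level permutation threshold
#'
#' Pools per-participant null samples and returns the empirical
#' `(1 - alpha)` quantile (nearest rank).
#'
#' @param null_samples list of numeric vectors (one per participant) or a
#'   single numeric vector.
#' @param alpha significance level, default 0.05.
#' @return A `SignificanceResult`: list with `threshold`, `alpha`,
#'   `method = "permutation"`, `null_distribution`, `n_permutations`.
#' @export
group_threshold <- function(null_samples, alpha = 0.05) {
  pooled <- sort(unname(unlist(null_samples)))
  if (length(pooled) == 0) stop("empty null distribution")
  k <- max(1L, ceiling((1 - alpha) * length(pooled)))
  structure(list(threshold = pooled[k], alpha = alpha,
                 method = "permutation", null_distribution = pooled,
                 n_permutations = length(pooled)),
            class = "SignificanceResult")
}

#' @export
print.SignificanceResult <- function(x, ...) {
  cat(sprintf("<SignificanceResult> %s threshold %.4f (alpha %.2f, n = %d)\n",
              x$method, x$threshold, x$alpha,
              x$n_permutations %||% NA_integer_))
  invisible(x)
}
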