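#' Sliding-window specification
#'
#' @param length window length in samples (default 20).
#' @param step step between window starts in samples (default 1, i.e. 19
#'   samples overlap at the default length).
#' @return A `window_spec` list.
#' @export
window_spec <- function(length = 20, step = 1) {
  if (!(step >= 1 && step <= length))
    stop("`step` must satisfy 1 <= step <= length")
  structure(list(length = as.integer(length), step = as.integer(step)),
            class = "window_spec")
}

#' Cross-validation plan
#'
#' Two modes: `"between_participants"` (stratified participant-wise k-fold
#' for group decoding) and `"within_participant"` (repeated stratified
#' shuffle splits of one participant's trials for stimulus decoding).
#'
#' @param mode `"between_participants"` or `"within_participant"`.
#' @param n_folds number of folds (between mode) or random splits (within
#'   mode); default 10.
#' @param subsample_to_minority logical; downsample every training class to
#'   the minority class count (between mode, default `TRUE`).
#' @param test_fraction held-out trial fraction per split (within mode,
#'   default 0.20).
#' @param seed integer seed governing shuffles and subsampling.
#' @return A `cv_plan` list.
#' @export
cv_plan <- function(mode = c("between_participants", "within_participant"),
                    n_folds = 10, subsample_to_minority = TRUE,
                    test_fraction = 0.20, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "within_participant" && !(test_fraction > 0 && test_fraction < 1))
    stop("`test_fraction` must be in (0, 1)")
  structure(list(mode = mode, n_folds = as.integer(n_folds),
                 subsample_to_minority = subsample_to_minority,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Stratified participant-wise cross-validation folds
#'
#' Partitions participants into `n_folds` folds, stratified by age group:
#' every participant is tested exactly once and per-group fold counts
#' differ by at most one. Remainder participants are placed on the folds
#' with the smallest running totals, so overall fold sizes are as equal as
#' possible (209 participants in 10 folds gives nine folds of 21 and one
#' of 20 — i.e. 188/189 participants for training).
#'
#' @param dataset list of [epoch_set()] objects.
#' @param plan a [cv_plan()] with mode `"between_participants"`.
#' @return list of folds, each `list(train = ids, test = ids)`.
#' @export
make_group_cv <- function(dataset, plan) {
  ids <- vapply(dataset, function(e) e$participant_id, "")
  grp <- vapply(dataset, function(e) e$group_label, "")
  k <- plan$n_folds
  counts <- table(grp)
  if (any(counts < k))
    stop("every group needs at least `n_folds` participants")
  fold_of <- integer(length(ids))
  extras <- integer(k) # running count of remainder assignments per fold
  gi <- 0L
  for (g in names(counts)) {
    gi <- gi + 1L
    members <- with_seed(derive_seed(plan$seed, 1L, gi),
                         sample(which(grp == g)))
    n <- length(members)
    base <- n %/% k
    r <- n %% k
    sizes <- rep(base, k)
    if (r > 0) {
      # prefer the currently least-loaded folds; deterministic tie-break
      pick <- order(extras, seq_len(k))[seq_len(r)]
      sizes[pick] <- sizes[pick] + 1L
      extras[pick] <- extras[pick] + 1L
    }
    at <- 0L
    for (f in seq_len(k)) {
      if (sizes[f] > 0) fold_of[members[at + seq_len(sizes[f])]] <- f
      at <- at + sizes[f]
    }
  }
  lapply(seq_len(k), function(f)
    list(train = ids[fold_of != f], test = ids[fold_of == f]))
}

#' Subsample training trials to the minority class
#'
#' @param group_labels per-trial class labels.
#' @param seed integer seed.
#' @return sorted integer indices of the retained trials; each class is
#'   downsampled without replacement to the minority-class count.
#' @export
subsample_training <- function(group_labels, seed) {
  if (!is.factor(group_labels)) group_labels <- factor(group_labels)
  counts <- table(group_labels)
  if (any(counts == 0)) stop("empty class in training labels")
  m <- min(counts)
  keep <- integer(0)
  for (ci in seq_along(levels(group_labels))) {
    idx <- which(group_labels == levels(group_labels)[ci])
    if (length(idx) > m)
      idx <- with_seed(derive_seed(seed, 2L, ci), sample(idx, m))
    keep <- c(keep, idx)
  }
  sort(keep)
}

#' Stratified random train/test splits within one participant
#'
#' `n_folds` independent stratified shuffle splits: per split, each
#' condition contributes test trials by largest-remainder allocation of
#' `round(n_total * test_fraction)`, so class proportions are preserved
#' within rounding and both conditions appear in every train and test set.
#'
#' @param epochs an [epoch_set()].
#' @param plan a [cv_plan()] with mode `"within_participant"`.
#' @return list of splits, each `list(train = idx, test = idx)`.
#' @export
make_within_splits <- function(epochs, plan) {
  labels <- factor(epochs$trial_labels)
  counts <- table(labels)
  if (any(counts < 5)) stop("need at least 5 trials per condition")
  n_tot <- sum(counts)
  n_test <- max(round(n_tot * plan$test_fraction), length(counts))
  per_class <- largest_remainder(as.numeric(counts) * n_test / n_tot, n_test)
  per_class <- pmax(1L, pmin(per_class, as.integer(counts) - 1L))
  lapply(seq_len(plan$n_folds), function(s) {
    test <- integer(0)
    for (ci in seq_along(levels(labels))) {
      idx <- which(labels == levels(labels)[ci])
      test <- c(test, with_seed(derive_seed(plan$seed, 3L, s, ci),
                                sample(idx, per_class[ci])))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n_tot), test), test = test)
  })
}

#' Radial-basis SVM with training-set standardisation
#'
#' Features are standardised by the training mean and standard deviation;
#' the kernel width defaults to `1 / (n_features * var)` with `var` the
#' pooled variance of the standardised training matrix, and the cost
#' parameter to 1.
#'
#' @param features numeric matrix, trials x features.
#' @param labels per-trial class labels (at least two classes).
#' @param cost SVM regularisation constant.
#' @param gamma kernel width; `NULL` uses the default above.
#' @return An `erp_classifier` object.
#' @export
train_classifier <- function(features, labels, cost = 1, gamma = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training labels contain a single class")
  n <- nrow(features)
  ctr <- colMeans(features)
  scl <- sqrt(pmax(colMeans(features^2) - ctr^2, 0) * n / (n - 1))
  scl[scl < .Machine$double.eps^0.5 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  if (is.null(gamma)) {
    v <- stats::var(as.vector(Z))
    gamma <- 1 / (ncol(Z) * ifelse(v > 0, v, 1))
  }
  model <- e1071::svm(Z, labels, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE, fitted = FALSE,
                      na.action = function(d) d)
  structure(list(model = model, center = ctr, scale = scl,
                 levels = levels(labels), gamma = gamma),
            class = "erp_classifier")
}

#' Predict classes and decision scores
#'
#' @param object an `erp_classifier`.
#' @param newdata numeric matrix, trials x features.
#' @param ... unused.
#' @return list with `class` (factor predictions) and, for binary
#'   problems, `score` (decision values oriented so that larger values
#'   favour the second class level).
#' @export
predict.erp_classifier <- function(object, newdata, ...) {
  Z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  p <- stats::predict(object$model, Z, decision.values = TRUE,
                      na.action = function(d) d)
  out <- list(class = factor(as.character(p), levels = object$levels))
  if (length(object$levels) == 2) {
    dv <- attr(p, "decision.values")
    first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    # libsvm's positive decision value favours the first-named class
    out$score <- if (first == object$levels[2]) dv[, 1] else -dv[, 1]
  }
  out
}

#' Rank-based AUC (Mann-Whitney with midrank tie correction)
#'
#' `AUC = U / (n1 * n0)` with the second factor level treated as the
#' positive class.
#'
#' @param scores numeric decision scores (larger = more positive class).
#' @param labels two-class labels.
#' @return proportion in `[0, 1]`.
#' @export
score_auc <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("AUC needs exactly two classes")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix with precision, recall and accuracy
#'
#' @param truth,pred factors of true and predicted labels on a common
#'   level set.
#' @return A `ConfusionResult`: list with `matrix` (rows = true class),
#'   `precision`, `recall` (per class), `accuracy`, `n`.
#' @export
confusion_result <- function(truth, pred) {
  lv <- union(levels(factor(truth)), levels(factor(pred)))
  truth <- factor(truth, levels = lv)
  pred <- factor(pred, levels = lv)
  m <- table(true = truth, predicted = pred)
  recall <- diag(m) / pmax(rowSums(m), 1)
  precision <- diag(m) / pmax(colSums(m), 1)
  structure(list(matrix = m, precision = precision, recall = recall,
                 accuracy = sum(diag(m)) / sum(m), n = sum(m)),
            class = "ConfusionResult")
}

#' @export
print.ConfusionResult <- function(x, ...) {
  cat(sprintf("<ConfusionResult> accuracy %.3f on %d trials\n", x$accuracy, x$n))
  print(x$matrix)
  invisible(x)
}

# window start indices and centre-sample times
window_positions <- function(times, window) {
  ns <- length(times)
  if (window$length > ns) stop("window longer than the epoch")
  starts <- seq.int(1L, ns - window$length + 1L, by = window$step)
  centers <- times[starts + ceiling(window$length / 2) - 1L]
  list(starts = starts, centers = centers)
}

flatten_features <- function(data3d, sample_idx = NULL) {
  if (!is.null(sample_idx)) data3d <- data3d[, , sample_idx, drop = FALSE]
  dim(data3d) <- c(dim(data3d)[1], dim(data3d)[2] * dim(data3d)[3])
  data3d
}

#' Whole-trial decoding of group membership
#'
#' Per fold: xDAWN filters are fitted on the (optionally minority-class
#' subsampled) training trials, both partitions are spatially filtered,
#' virtual channels x all samples are flattened into the feature vector,
#' and an RBF-SVM predicts the pooled test trials. The confusion matrix is
#' aggregated over folds.
#'
#' @param dataset list of preprocessed [epoch_set()] objects.
#' @param plan a [cv_plan()] (between-participants mode).
#' @param n_components xDAWN components per class.
#' @param use_xdawn set `FALSE` to decode raw channels (benchmark baseline).
#' @param cost,gamma passed to [train_classifier()].
#' @return A `ConfusionResult` with an extra `fold_accuracy` vector.
#' @export
decode_whole_trial <- function(dataset, plan, n_components = 5,
                               use_xdawn = TRUE, cost = 1, gamma = NULL) {
  folds <- make_group_cv(dataset, plan)
  pool <- pool_trials(dataset)
  lv <- unique(vapply(dataset, function(e) e$group_label, ""))
  truth_all <- factor(character(0), levels = lv)
  pred_all <- factor(character(0), levels = lv)
  fold_acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    tr <- pool$participant %in% folds[[f]]$train
    te <- pool$participant %in% folds[[f]]$test
    ytr <- factor(pool$group[tr], levels = lv)
    keep <- seq_len(sum(tr))
    if (plan$subsample_to_minority)
      keep <- subsample_training(ytr, derive_seed(plan$seed, 4L, f))
    tr_idx <- which(tr)[keep]
    ytr <- factor(pool$group[tr_idx], levels = lv)
    yte <- factor(pool$group[te], levels = lv)
    ep_tr <- epoch_set(pool$data[tr_idx, , , drop = FALSE], pool$sfreq,
                       pool$times, ytr)
    ep_te <- epoch_set(pool$data[te, , , drop = FALSE], pool$sfreq,
                       pool$times, yte)
    if (use_xdawn) {
      fs <- xdawn_fit(ep_tr, ytr, n_components)
      ep_tr <- xdawn_transform(fs, ep_tr)
      ep_te <- xdawn_transform(fs, ep_te)
    }
    clf <- train_classifier(flatten_features(ep_tr$data), ytr,
                            cost = cost, gamma = gamma)
    pr <- predict(clf, flatten_features(ep_te$data))$class
    truth_all <- factor(c(as.character(truth_all), as.character(yte)),
                        levels = lv)
    pred_all <- factor(c(as.character(pred_all), as.character(pr)),
                       levels = lv)
    fold_acc[f] <- mean(pr == yte)
  }
  res <- confusion_result(truth_all, pred_all)
  res$fold_accuracy <- fold_acc
  res
}

new_trajectory <- function(window_centers, scores, metric) {
  nf <- ncol(scores)
  mean_curve <- rowMeans(scores)
  sdv <- apply(scores, 1, stats::sd)
  structure(
    list(window_centers = window_centers, scores = scores, metric = metric,
         fold_details = nf, mean_curve = mean_curve,
         ci95 = 1.96 * sdv / sqrt(nf)),
    class = "DecodeTrajectory")
}

#' @export
print.DecodeTrajectory <- function(x, ...) {
  i <- which.max(x$mean_curve)
  cat(sprintf(
    "<DecodeTrajectory> %d windows x %d folds (%s); peak %.3f at %.0f ms\n",
    length(x$window_centers), x$fold_details, x$metric,
    x$mean_curve[i], 1000 * x$window_centers[i]))
  invisible(x)
}

#' Time-resolved decoding
#'
#' Sliding-window classification: xDAWN is fitted once per fold on the
#' full-length training epochs, trials are spatially filtered, and a fresh
#' RBF-SVM is trained and scored on each window of `window$length` samples
#' (features = virtual channels x window samples). With step 1 the number
#' of windows is `n_samples - length + 1` (212 for 231-sample epochs at
#' the default 20-sample window).
#'
#' `x` may be a single [epoch_set()] (within-participant stimulus decoding,
#' AUC metric, stratified shuffle splits) or a list of epoch sets
#' (between-participant group decoding, accuracy metric, participant-wise
#' folds with minority-class subsampling).
#'
#' @param x an `EpochSet` or list of them.
#' @param plan a [cv_plan()] matching the mode implied by `x`.
#' @param window a [window_spec()].
#' @param n_components xDAWN components per class.
#' @param metric `"auc"` (binary only) or `"accuracy"`.
#' @param use_xdawn set `FALSE` to decode raw channels.
#' @param labels optional per-trial labels overriding the condition labels
#'   (within mode; used by the permutation machinery).
#' @param cost,gamma passed to [train_classifier()].
#' @return A `DecodeTrajectory`.
#' @export
decode_time_resolved <- function(x, plan, window = window_spec(),
                                 n_components = 5,
                                 metric = c("auc", "accuracy"),
                                 use_xdawn = TRUE, labels = NULL,
                                 cost = 1, gamma = NULL) {
  metric <- match.arg(metric)
  if (inherits(x, "EpochSet"))
    decode_within_tr(x, plan, window, n_components, metric, use_xdawn,
                     labels, cost, gamma)
  else
    decode_between_tr(x, plan, window, n_components, metric, use_xdawn,
                      cost, gamma)
}

decode_within_tr <- function(epochs, plan, window, n_components, metric,
                             use_xdawn, labels, cost, gamma) {
  labels <- factor(labels %||% epochs$trial_labels)
  ep <- epochs
  ep$trial_labels <- labels
  splits <- make_within_splits(ep, plan)
  wp <- window_positions(ep$times, window)
  scores <- matrix(NA_real_, length(wp$starts), length(splits))
  for (s in seq_along(splits)) {
    tr <- splits[[s]]$train; te <- splits[[s]]$test
    ep_tr <- subset_trials(ep, tr); ep_te <- subset_trials(ep, te)
    if (use_xdawn) {
      fs <- xdawn_fit(ep_tr, ep_tr$trial_labels, n_components)
      ep_tr <- xdawn_transform(fs, ep_tr)
      ep_te <- xdawn_transform(fs, ep_te)
    }
    for (w in seq_along(wp$starts)) {
      idx <- wp$starts[w] + seq_len(window$length) - 1L
      clf <- train_classifier(flatten_features(ep_tr$data, idx),
                              ep_tr$trial_labels, cost = cost, gamma = gamma)
      pr <- predict(clf, flatten_features(ep_te$data, idx))
      scores[w, s] <- if (metric == "auc")
        score_auc(pr$score, ep_te$trial_labels)
      else mean(pr$class == ep_te$trial_labels)
    }
  }
  new_trajectory(wp$centers, scores, metric)
}

decode_between_tr <- function(dataset, plan, window, n_components, metric,
                              use_xdawn, cost, gamma) {
  if (metric == "auc" &&
      length(unique(vapply(dataset, function(e) e$group_label, ""))) != 2)
    stop("AUC metric requires exactly two groups")
  folds <- make_group_cv(dataset, plan)
  pool <- pool_trials(dataset)
  lv <- unique(vapply(dataset, function(e) e$group_label, ""))
  wp <- window_positions(pool$times, window)
  scores <- matrix(NA_real_, length(wp$starts), length(folds))
  for (f in seq_along(folds)) {
    tr <- which(pool$participant %in% folds[[f]]$train)
    te <- which(pool$participant %in% folds[[f]]$test)
    ytr <- factor(pool$group[tr], levels = lv)
    if (plan$subsample_to_minority) {
      keep <- subsample_training(ytr, derive_seed(plan$seed, 4L, f))
      tr <- tr[keep]
      ytr <- factor(pool$group[tr], levels = lv)
    }
    yte <- factor(pool$group[te], levels = lv)
    ep_tr <- epoch_set(pool$data[tr, , , drop = FALSE], pool$sfreq,
                       pool$times, ytr)
    ep_te <- epoch_set(pool$data[te, , , drop = FALSE], pool$sfreq,
                       pool$times, yte)
    if (use_xdawn) {
      fs <- xdawn_fit(ep_tr, ytr, n_components)
      ep_tr <- xdawn_transform(fs, ep_tr)
      ep_te <- xdawn_transform(fs, ep_te)
    }
    for (w in seq_along(wp$starts)) {
      idx <- wp$starts[w] + seq_len(window$length) - 1L
      clf <- train_classifier(flatten_features(ep_tr$data, idx), ytr,
                              cost = cost, gamma = gamma)
      pr <- predict(clf, flatten_features(ep_te$data, idx))
      scores[w, f] <- if (metric == "auc") score_auc(pr$score, yte)
        else mean(pr$class == yte)
    }
  }
  new_trajectory(wp$centers, scores, metric)
}
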