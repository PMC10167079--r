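test_that("participant-wise stratified folds have the study's geometry", {
  ds <- dummy_dataset(c(children = 46, young = 39, earlyma = 21,
                        latema = 25, old = 40, veryold = 38))
  folds <- make_group_cv(ds, cv_plan("between_participants", 10, seed = 3))
  test_sizes <- vapply(folds, function(f) length(f$test), 1L)
  train_sizes <- vapply(folds, function(f) length(f$train), 1L)
  # modal fold: 21 participants tested, 188 trained
  expect_equal(as.integer(names(which.max(table(test_sizes)))), 21L)
  expect_equal(as.integer(names(which.max(table(train_sizes)))), 188L)
  # every participant tests exactly once
  all_test <- unlist(lapply(folds, function(f) f$test))
  expect_setequal(all_test, vapply(ds, function(e) e$participant_id, ""))
  expect_equal(length(all_test), 209L)
  # per-group fold counts differ by <= 1
  grp_of <- setNames(vapply(ds, function(e) e$group_label, ""),
                     vapply(ds, function(e) e$participant_id, ""))
  for (f in folds) {
    per_group <- table(grp_of[f$test])
    expect_true(all(per_group >= floor(c(46, 21, 25, 40, 38, 39) / 10)))
  }
  counts <- sapply(folds, function(f) table(factor(grp_of[f$test])))
  for (g in rownames(counts))
    expect_lte(max(counts[g, ]) - min(counts[g, ]), 1)
})

test_that("fold construction handles boundary group sizes", {
  # 10 participants in one group, 10 folds -> leave-one-out
  loo <- make_group_cv(dummy_dataset(c(g1 = 10)),
                       cv_plan("between_participants", 10, seed = 1))
  expect_true(all(vapply(loo, function(f) length(f$test), 1L) == 1L))
  # exact divisibility: 2 groups x 20 participants -> always 2 + 2
  folds <- make_group_cv(dummy_dataset(c(a = 20, b = 20)),
                         cv_plan("between_participants", 10, seed = 1))
  expect_true(all(vapply(folds, function(f) length(f$test), 1L) == 4L))
  expect_error(make_group_cv(dummy_dataset(c(a = 4)),
                             cv_plan("between_participants", 10)),
               "n_folds")
})

test_that("training subsampling equalises class counts", {
  labs <- rep(c("a", "b", "c"), c(100, 60, 60))
  idx <- subsample_training(labs, seed = 4)
  expect_equal(as.vector(table(labs[idx])), c(60, 60, 60))
  expect_identical(idx, subsample_training(labs, seed = 4))  # deterministic
  # equal classes: identity
  labs_eq <- rep(c("a", "b"), each = 30)
  expect_identical(subsample_training(labs_eq, seed = 1), 1:60)
  expect_error(subsample_training(factor("a", levels = c("a", "b")), 1),
               "empty class")
})

test_that("within-participant splits are stratified at the test fraction", {
  mk <- function(nc, ni) epoch_set(array(0, c(nc + ni, 1, 4)), 64,
                                   seq(0, 3) / 64,
                                   rep(c("congruent", "incongruent"),
                                       c(nc, ni)))
  plan <- cv_plan("within_participant", 10, test_fraction = 0.2, seed = 2)
  sp <- make_within_splits(mk(80, 80), plan)
  expect_length(sp, 10)
  for (s in sp) {
    labs <- rep(c("congruent", "incongruent"), c(80, 80))
    expect_equal(as.vector(table(labs[s$test])), c(16, 16))
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), 1:160)
    expect_equal(nlevels(factor(labs[s$train])), 2)
  }
  # 143 trials at 0.20 -> about 29 test trials, as in the study
  sp143 <- make_within_splits(mk(72, 71), plan)
  expect_equal(length(sp143[[1]]$test), 29L)
  expect_error(cv_plan("within_participant", test_fraction = 0),
               "test_fraction")
  expect_error(make_within_splits(mk(4, 80), plan), "5 trials")
})

test_that("the RBF-SVM wrapper behaves on canonical toy problems", {
  set.seed(1)
  blob <- function(n, mu) sweep(matrix(rnorm(n * 2), n, 2), 2, mu, "+")
  X <- rbind(blob(20, c(-6, 0)), blob(20, c(6, 0)))
  y <- rep(c("a", "b"), each = 20)
  clf <- train_classifier(X, y)
  pr <- predict(clf, X)
  expect_equal(mean(pr$class == y), 1)                # separable
  expect_equal(score_auc(pr$score, factor(y)), 1)
  # a label-shuffled model scores random held-out labels at chance
  Xte <- rbind(blob(100, c(-6, 0)), blob(100, c(6, 0)))
  yte_null <- sample(rep(c("a", "b"), each = 100))
  acc_null <- mean(predict(train_classifier(X, sample(y)), Xte)$class ==
                     yte_null)
  band <- qbinom(c(0.025, 0.975), 200, 0.5) / 200
  expect_gte(acc_null, band[1])
  expect_lte(acc_null, band[2])
  # duplicating every training point leaves the decision rule alone
  clf2 <- train_classifier(rbind(X, X), c(y, y))
  expect_identical(predict(clf2, Xte)$class, predict(clf, Xte)$class)
  expect_equal(predict(clf2, Xte)$score, predict(clf, Xte)$score,
               tolerance = 0.1)
  expect_error(train_classifier(X, rep("a", 40)), "single class")
})

test_that("rank-based AUC equals the Mann-Whitney statistic", {
  expect_equal(score_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(score_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0)
  expect_equal(score_auc(rep(0.5, 4), c(0, 0, 1, 1)), 0.5)  # midrank ties
  set.seed(9)
  s <- round(rnorm(40), 1)  # rounding forces ties
  l <- rep(c(0, 1), 20)
  u <- unname(wilcox.test(s[l == 1], s[l == 0], exact = FALSE)$statistic)
  expect_equal(score_auc(s, l), u / (20 * 20))
  expect_error(score_auc(1:4, rep("a", 4)), "two classes")
})

test_that("window counts follow the sliding-window formula", {
  for (ns in c(59, 100, 231)) {
    for (len in c(5, 20)) {
      for (st in c(1, 2, 5)) {
        if (st > len || len > ns) next
        wp <- erpdecode:::window_positions(seq(0, ns - 1) / 256,
                                           window_spec(len, st))
        expect_equal(length(wp$starts), floor((ns - len) / st) + 1)
      }
    }
  }
  # the study's geometry: 231 samples, 20-point windows, 19 overlap
  wp <- erpdecode:::window_positions(seq(0, 230) / 256, window_spec(20, 1))
  expect_equal(length(wp$starts), 212L)
  expect_error(erpdecode:::window_positions(seq(0, 9) / 64,
                                            window_spec(20, 1)),
               "longer than the epoch")
})

test_that("noise-free separable groups decode perfectly", {
  cfg <- twogroup_config(n_per_group = 4, n_trials = 12, noise_sd = 0,
                         seed = 21, jitter = FALSE)
  ds <- simulate_dataset(cfg)
  plan <- cv_plan("between_participants", 4, seed = 2)
  res <- decode_whole_trial(ds, plan, n_components = 2)
  expect_equal(res$accuracy, 1)
  expect_true(all(res$matrix[row(res$matrix) != col(res$matrix)] == 0))
  expect_equal(unname(res$precision), c(1, 1))
  expect_equal(unname(res$recall), c(1, 1))
  # accuracy equals trace / total of the pooled confusion matrix
  expect_equal(res$accuracy, sum(diag(res$matrix)) / sum(res$matrix))
  expect_equal(res$accuracy, mean(res$fold_accuracy))
})

test_that("a time-localised condition effect is recovered in time", {
  ep <- condition_effect_participant(n_per_cond = 40, delta = -4,
                                     effect_latency = 400, noise_sd = 2,
                                     seed = 31)
  plan <- cv_plan("within_participant", 5, seed = 3)
  tr <- decode_time_resolved(ep, plan, window_spec(8, 2), n_components = 2)
  expect_s3_class(tr, "DecodeTrajectory")
  expect_true(all(tr$scores >= 0 & tr$scores <= 1))
  expect_equal(length(tr$mean_curve), length(tr$window_centers))
  pk <- extract_peak(tr)
  expect_gt(pk$max_score, 0.8)
  expect_gt(pk$peak_time, 0.36)
  expect_lt(pk$peak_time, 0.44)
})

test_that("group decoding accuracy grows with simulated SNR", {
  accs <- vapply(c(0, 0.5, 1, 2), function(snr) {
    cfg <- twogroup_config(n_per_group = 4, n_trials = 24, noise_sd = 4,
                           snr_scale = snr, seed = 13)
    decode_whole_trial(simulate_dataset(cfg),
                       cv_plan("between_participants", 4, seed = 5),
                       n_components = 2)$accuracy
  }, 1.0)
  expect_true(all(diff(accs) >= 0))
  expect_lt(accs[1], 0.65)   # chance-level at zero SNR
  expect_gt(accs[4], 0.9)
})

test_that("xDAWN filtering does not hurt accuracy at low SNR", {
  # seeded benchmark aggregated over two sub-unity SNR levels
  diffs <- vapply(c(0.5, 1), function(snr) {
    cfg <- twogroup_config(n_per_group = 6, n_trials = 30, noise_sd = 5,
                           snr_scale = snr, seed = 17)
    ds <- simulate_dataset(cfg)
    plan <- cv_plan("between_participants", 3, seed = 6)
    decode_whole_trial(ds, plan, n_components = 2)$accuracy -
      decode_whole_trial(ds, plan, use_xdawn = FALSE)$accuracy
  }, 1.0)
  expect_gte(sum(diffs), 0)
})
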