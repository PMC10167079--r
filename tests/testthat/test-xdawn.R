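# Brute-force generalized eigendecomposition oracle for (S, T):
# eigen of solve(T) %*% S, eigenvalues descending.
ge_oracle <- function(S, T) {
  eg <- eigen(solve(T) %*% S)
  ord <- order(Re(eg$values), decreasing = TRUE)
  list(values = Re(eg$values)[ord],
       vectors = apply(Re(eg$vectors[, ord, drop = FALSE]), 2,
                       function(v) v / sqrt(sum(v^2))))
}

# covariances exactly as defined: class-evoked signal vs trial-average total
covs_from_epochs <- function(ep, class) {
  ns <- n_samples(ep)
  E <- apply(ep$data[ep$trial_labels == class, , , drop = FALSE],
             c(2, 3), mean)
  S <- E %*% t(E) / ns
  T <- matrix(0, n_channels(ep), n_channels(ep))
  for (i in seq_len(n_trials(ep))) {
    X <- ep$data[i, , ]
    T <- T + X %*% t(X)
  }
  list(S = S, T = T / (n_trials(ep) * ns))
}

test_that("a separable two-channel evoked yields the obvious filter", {
  # class signal lives entirely on channel 1; channel 2 is silent
  t <- seq(0, 0.5 - 1 / 64, by = 1 / 64)
  sig <- sin(2 * pi * 4 * t)
  data <- array(0, c(8, 2, length(t)))
  for (i in 1:4) data[i, 1, ] <- sig          # class A trials
  for (i in 5:8) data[i, 1, ] <- 0.2 * sig    # class B trials
  ep <- epoch_set(data, 64, t, rep(c("congruent", "incongruent"), each = 4))
  fs <- xdawn_fit(ep, n_components = 1)
  w <- fs$filters[["congruent"]][1, ]
  expect_equal(abs(w[1]), 1, tolerance = 1e-8)
  expect_equal(w[2], 0, tolerance = 1e-8)
  virt <- xdawn_transform(fs, ep)
  expect_equal(abs(cor(virt$data[1, 1, ], sig)), 1, tolerance = 1e-10)
})

test_that("fitted eigenpairs solve the generalized eigenproblem", {
  set.seed(42)
  nc <- 8; ns <- 40; ntr <- 30
  mix <- rnorm(nc) * 0.5   # evoked power below noise so the ratio stays < 1
  evoked <- sin(2 * pi * 3 * seq(0, ns - 1) / ns)
  data <- array(rnorm(ntr * nc * ns, sd = 1), c(ntr, nc, ns))
  labs <- rep(c("congruent", "incongruent"), length.out = ntr)
  for (i in which(labs == "incongruent"))
    data[i, , ] <- data[i, , ] + mix %o% evoked
  ep <- epoch_set(data, 64, seq(0, ns - 1) / 64, labs)
  fs <- xdawn_fit(ep, n_components = 3)
  cv <- covs_from_epochs(ep, "incongruent")
  orc <- ge_oracle(cv$S, cv$T)
  # residual of the eigen equation for every fitted component
  for (k in 1:3) {
    w <- fs$filters[["incongruent"]][k, ]
    lam <- fs$eigenvalues[["incongruent"]][k]
    expect_lt(max(abs(cv$S %*% w - lam * cv$T %*% w)), 1e-8)
  }
  # eigenvalues match the dense oracle, sorted descending in [0, 1]
  expect_equal(fs$eigenvalues[["incongruent"]], orc$values[1:3],
               tolerance = 1e-8)
  ev <- fs$eigenvalues[["incongruent"]]
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(ev >= 0 & ev <= 1))
  # leading subspace agrees with the oracle (principal angle ~ 0)
  w1 <- fs$filters[["incongruent"]][1, ]
  expect_equal(abs(sum(w1 * orc$vectors[, 1])), 1, tolerance = 1e-6)
})

test_that("no direction beats the leading Rayleigh quotient", {
  set.seed(7)
  data <- array(rnorm(20 * 6 * 30), c(20, 6, 30))
  data[11:20, 2, ] <- data[11:20, 2, ] + 2
  ep <- epoch_set(data, 64, seq(0, 29) / 64,
                  rep(c("congruent", "incongruent"), each = 10))
  fs <- xdawn_fit(ep, n_components = 1)
  cv <- covs_from_epochs(ep, "incongruent")
  lam1 <- fs$eigenvalues[["incongruent"]][1]
  rq <- replicate(2000, {
    v <- rnorm(6)
    as.numeric(t(v) %*% cv$S %*% v / (t(v) %*% cv$T %*% v))
  })
  expect_true(all(rq <= lam1 + 1e-9))
})

test_that("transform produces class x component virtual channels", {
  cfg <- twogroup_config(n_per_group = 2, n_trials = 12, seed = 3)
  ep <- simulate_participant(cfg, cfg$groups[[1]], 1)
  fs <- xdawn_fit(ep, n_components = 5)
  expect_equal(n_channels(xdawn_transform(fs, ep)), 10L)  # 2 classes x 5
  # six classes x 5 components -> 30 virtual channels
  labs6 <- factor(rep(paste0("g", 1:6), length.out = n_trials(ep)))
  fs6 <- xdawn_fit(ep, labels = labs6, n_components = 5)
  expect_equal(n_channels(xdawn_transform(fs6, ep)), 30L)
  # rows are unit norm
  for (cl in fs$class_labels)
    expect_equal(rowSums(fs$filters[[cl]]^2), rep(1, 5), tolerance = 1e-10)
  expect_error(xdawn_fit(ep, n_components = 20), "n_components")
  expect_error(xdawn_fit(ep, labels = c("a", rep("b", n_trials(ep) - 1))),
               "2 trials")
  expect_error(xdawn_transform(fs, signal_epochs(matrix(0, 2, 10), 64)),
               "channel count")
})

test_that("a full filter set is an invertible basis", {
  set.seed(11)
  data <- array(rnorm(12 * 5 * 25), c(12, 5, 25))
  ep <- epoch_set(data, 64, seq(0, 24) / 64,
                  rep(c("congruent", "incongruent"), 6))
  fs <- xdawn_fit(ep, n_components = 5)
  W <- fs$filters[["congruent"]]
  X <- ep$data[3, , ]
  expect_lt(max(abs(solve(W) %*% (W %*% X) - X)), 1e-6)
})

test_that("test data never influence the fitted filters", {
  cfg <- twogroup_config(n_per_group = 2, n_trials = 16, seed = 5)
  ep <- simulate_participant(cfg, cfg$groups[[1]], 2)
  train <- subset_trials(ep, 1:10)
  test <- subset_trials(ep, 11:16)
  fs <- xdawn_fit(train, n_components = 2)
  out1 <- xdawn_transform(fs, test)
  test_relabelled <- test
  test_relabelled$trial_labels <- rev(test$trial_labels)
  out2 <- xdawn_transform(fs, test_relabelled)
  expect_identical(out1$data, out2$data)
})

test_that("filter sets survive a JSON round trip", {
  cfg <- twogroup_config(n_per_group = 2, n_trials = 12, seed = 8)
  ep <- simulate_participant(cfg, cfg$groups[[1]], 3)
  fs <- xdawn_fit(ep, n_components = 3)
  path <- tempfile(fileext = ".json")
  xdawn_to_json(fs, path)
  fs2 <- xdawn_from_json(path)
  expect_equal(fs2$filters, fs$filters, tolerance = 1e-12)
  expect_equal(fs2$eigenvalues, lapply(fs$eigenvalues, identity),
               tolerance = 1e-12)
  expect_identical(fs2$class_labels, fs$class_labels)
})
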