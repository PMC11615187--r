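test_that("lagged dataset construction counts rows and columns correctly", {
  tcs <- array(rnorm(2L * 12L * 1L), c(2L, 12L, 1L))
  d <- build_lagged_dataset(tcs, 10L)
  expect_equal(dim(d$X), c(2L, 20L))
  expect_equal(dim(d$Y), c(2L, 2L))
  tcs2 <- array(rnorm(2L * 12L * 2L), c(2L, 12L, 2L))
  d2 <- build_lagged_dataset(tcs2, 10L)
  expect_equal(nrow(d2$X), 4L)             # no cross-boundary rows
  expect_equal(d2$trial, c(1L, 1L, 2L, 2L))
  expect_error(build_lagged_dataset(array(1, c(2L, 50L, 1L)), 3L), "constant")
})

test_that("design columns are exactly standardized and ordered node-major", {
  set.seed(1)
  tcs <- array(rnorm(3L * 200L * 2L), c(3L, 200L, 2L))
  d <- build_lagged_dataset(tcs, 4L)
  expect_lt(max(abs(colMeans(d$X))), 1e-8)
  expect_lt(max(abs(apply(d$X, 2L, sd) - 1)), 1e-8)
  # column (j-1)p + d holds node j at lag d: lag-1 column of node 2
  raw <- tcs[2L, 4L:199L, 1L]
  expect_gt(cor(d$X[1:196, (2L - 1L) * 4L + 1L], raw), 0.999)
})

test_that("a hand-set one-neuron network yields the textbook connectivity value", {
  model <- list(W1 = matrix(c(0.5, -0.3), 1L, 2L), b1 = 0,
                W2 = matrix(1, 1L, 1L), b2 = 0)
  out <- extract_linear_connectivity(model, M = 1L, p = 2L)
  expect_equal(out$A[[1L]][1L, 1L], 0.5)
  expect_equal(out$A[[2L]][1L, 1L], -0.3)
  expect_equal(out$lC[1L, 1L], 0.4)
  zero <- list(W1 = matrix(rnorm(20L), 10L, 2L), b1 = rnorm(10L),
               W2 = matrix(0, 1L, 10L), b2 = 0)
  expect_true(all(extract_linear_connectivity(zero, M = 1L, p = 2L)$lC == 0))
})

test_that("training is bit-reproducible given the same seed", {
  set.seed(2)
  tcs <- array(rnorm(2L * 150L * 2L), c(2L, 150L, 2L))
  d <- build_lagged_dataset(tcs, 2L)
  m1 <- train_network(d, H = 4L, folds = 2L, max_epochs = 20L, seed = 7L)
  m2 <- train_network(d, H = 4L, folds = 2L, max_epochs = 20L, seed = 7L)
  expect_identical(m1$folds[[1L]]$W1, m2$folds[[1L]]$W1)
  expect_identical(m1$folds[[2L]]$W2, m2$folds[[2L]]$W2)
})

test_that("destroying the lag structure removes all predictability", {
  A <- fixture_var2_A()
  sim <- simulate_nmvar(nmvar_spec(3L, 2L, A, n_samples = 2000L, seed = 3L))
  d <- build_lagged_dataset(nmvar_tcs(sim), 2L)
  set.seed(4)
  d$Y <- d$Y[sample.int(nrow(d$Y)), , drop = FALSE]
  m <- train_network(d, folds = 2L, seed = 5L)
  expect_lt(mean(vapply(m$folds, `[[`, numeric(1), "r2_test")), 0.05)
})

test_that("validation metrics match their definitions", {
  set.seed(6)
  d <- build_lagged_dataset(array(rnorm(2L * 300L), c(2L, 300L, 1L)), 2L)
  perfect <- list(W1 = matrix(0, 1L, 4L), b1 = 0, W2 = matrix(0, 2L, 1L),
                  b2 = c(0, 0))
  # mean predictor: R2 = 0 (targets are centered)
  v <- validate_model(perfect, d, seq_len(nrow(d$X)))
  expect_equal(v$r2, 0, tolerance = 1e-12)
  expect_equal(v$mse, mean(d$Y^2))
  expect_error(validate_model(perfect, d, integer()), "empty")
})

test_that("restricting a node with no incoming weights leaves NC at zero", {
  set.seed(7)
  tcs <- array(rnorm(2L * 200L), c(2L, 200L, 1L))
  d <- build_lagged_dataset(tcs, 1L)
  H <- 4L
  model <- list(W1 = cbind(matrix(rnorm(H), H, 1L), matrix(0, H, 1L)),
                b1 = rnorm(H), W2 = matrix(rnorm(2L * H), 2L, H),
                b2 = c(0, 0))
  NC <- extract_nonlinear_connectivity(model, d, rows = seq_len(nrow(d$X)))
  expect_equal(NC[, 2L], c(0, 0), tolerance = 1e-12)
})

test_that("linear VAR data is fit to OLS accuracy and NC stays near zero", {
  A <- list(matrix(c(0.5, 0.8, 0, 0.3), 2L, 2L))
  sim <- simulate_nmvar(nmvar_spec(2L, 1L, A, n_samples = 8000L, seed = 8L))
  tcs <- nmvar_tcs(sim)
  d <- build_lagged_dataset(tcs, 1L)
  fit <- ncreann_fit(tcs, 1L, folds = 2L, seed = 9L)
  ols <- ncreann:::ols_var_fit(d)
  expect_lt(mean(abs(fit$A[[1L]] - ols$A)), 0.05)
  expect_gt(fit$lC[2L, 1L], 5 * fit$lC[1L, 2L])
  expect_lt(mean(fit$mse_test), 1.1 * ols$mse)
  expect_lt(max(abs(fit$NC)), 0.08)
})

test_that("connectivity is invariant to doubling all node amplitudes", {
  A <- fixture_var2_A()
  sim <- simulate_nmvar(nmvar_spec(3L, 2L, A, n_samples = 1500L, seed = 10L))
  tcs <- nmvar_tcs(sim)
  f1 <- ncreann_fit(tcs, 2L, folds = 2L, seed = 11L)
  f2 <- ncreann_fit(2 * tcs, 2L, folds = 2L, seed = 11L)
  expect_identical(f1$lC, f2$lC)
  expect_identical(f1$NC, f2$NC)
})

test_that("relabeling nodes permutes the connectivity matrices accordingly", {
  A <- fixture_var2_A()
  sim <- simulate_nmvar(nmvar_spec(3L, 2L, A, n_samples = 6000L, seed = 12L))
  tcs <- nmvar_tcs(sim)
  perm <- c(3L, 1L, 2L)
  f1 <- ncreann_fit(tcs, 2L, folds = 2L, seed = 13L)
  f2 <- ncreann_fit(tcs[perm, , , drop = FALSE], 2L, folds = 2L, seed = 13L)
  # training is stochastic, so equivariance holds statistically
  expect_lt(mean(abs(f2$lC - f1$lC[perm, perm])), 0.05)
  expect_gt(cor(as.vector(f2$lC), as.vector(f1$lC[perm, perm])), 0.95)
})

test_that("model order selection finds the true order and handles edge cases", {
  A3 <- list(matrix(c(0.4, 0.3, 0, 0, 0.3, 0.2, 0, 0, 0.3), 3L, 3L),
             diag(0.15, 3L), diag(0.2, 3L))
  hits <- vapply(1:2, function(s) {
    sim <- simulate_nmvar(nmvar_spec(3L, 3L, A3, n_samples = 20000L, seed = s))
    mo <- select_model_order(nmvar_tcs(sim), 5L)
    mo$p_aic == 3L && mo$p_bic == 3L
  }, logical(1))
  expect_true(all(hits))
  wn <- simulate_nmvar(nmvar_spec(2L, 1L, list(matrix(0, 2L, 2L)),
                                  n_samples = 5000L, seed = 20L))
  expect_equal(select_model_order(nmvar_tcs(wn), 4L)$p_bic, 1L)
  one <- simulate_nmvar(nmvar_spec(2L, 1L, list(diag(0.4, 2L)),
                                   n_samples = 500L, seed = 21L))
  expect_equal(select_model_order(nmvar_tcs(one), 1L)$p, 1L)
})

test_that("time-shifted surrogates detect a strong linear coupling", {
  A <- list(matrix(c(0.5, 0.8, 0, 0.3), 2L, 2L))
  sim <- simulate_nmvar(nmvar_spec(2L, 1L, A, n_samples = 400L, n_trials = 2L,
                                   seed = 30L))
  sur <- surrogate_significance(nmvar_tcs(sim), p = 1L, folds = 2L,
                                n_surrogates = 60L, seed = 31L)
  expect_true(sur$lc_significant[2L, 1L])
  expect_warning(surrogate_significance(nmvar_tcs(sim), p = 1L, folds = 2L,
                                        n_surrogates = 5L, seed = 32L),
                 "unstable")
})
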