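test_that("AR(1) simulation reproduces the closed-form lag-1 autocorrelation", {
  spec <- nmvar_spec(1L, 1L, list(matrix(0.5)), noise_sd = 1,
                     n_samples = 10000L, seed = 42L)
  sim <- simulate_nmvar(spec)
  x <- sim$data[1L, 1L, ]
  r1 <- cor(x[-1L], x[-length(x)])
  expect_lt(abs(r1 - 0.5), 0.03)
})

test_that("the edge list marks exactly the planted couplings", {
  A <- list(matrix(c(0.5, 0.8, 0, 0.3), 2L, 2L))   # a21 = 0.8, a12 = 0
  sim <- simulate_nmvar(nmvar_spec(2L, 1L, A, n_samples = 50L, seed = 1L))
  lin <- sim$edges[sim$edges$type == "linear", ]
  expect_equal(nrow(lin), 1L)
  expect_equal(c(lin$from, lin$to), c(1L, 2L))
  nlsim <- simulate_nmvar(fixture_nonlinear(n_samples = 50L))
  expect_true(any(nlsim$edges$type == "nonlinear" &
                  nlsim$edges$from == 2L & nlsim$edges$to == 3L))
})

test_that("non-stationary coefficient stacks are rejected", {
  expect_error(nmvar_spec(1L, 1L, list(matrix(1.01))), "non-stationary")
})

test_that("a square coupling leaves variance an OLS VAR cannot explain", {
  sim <- simulate_nmvar(fixture_nonlinear(n_samples = 5000L, seed = 7L))
  x <- sim$data[1L, , ]
  n <- ncol(x)
  y3 <- x[3L, 2L:n]
  X <- cbind(x[1L, 1L:(n - 1L)], x[2L, 1L:(n - 1L)], x[3L, 1L:(n - 1L)])
  rv_lin <- mean(resid(lm(y3 ~ X))^2)
  rv_aug <- mean(resid(lm(y3 ~ X + I(X[, 2L]^2)))^2)
  expect_gt(rv_lin, 1.5 * rv_aug)
})

test_that("OLS recovers the planted linear coefficients from long simulations", {
  A <- fixture_var2_A()
  errs <- vapply(1:3, function(s) {
    sim <- simulate_nmvar(nmvar_spec(3L, 2L, A, n_samples = 20000L, seed = s))
    x <- sim$data[1L, , ]
    n <- ncol(x)
    # independent lag construction + raw-scale OLS
    Y <- t(x[, 3L:n])
    X <- cbind(t(x[, 2L:(n - 1L)]), t(x[, 1L:(n - 2L)]))
    B <- qr.solve(X, Y)
    Ahat <- list(t(B[1:3, ]), t(B[4:6, ]))
    max(abs(Ahat[[1L]] - A[[1L]]), abs(Ahat[[2L]] - A[[2L]]))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("generation is bit-reproducible given the same spec and seed", {
  spec <- fixture_nonlinear(n_samples = 200L, seed = 11L)
  expect_identical(simulate_nmvar(spec)$data, simulate_nmvar(spec)$data)
  sm <- synthetic_source_model(seed = 3L)
  tc <- matrix(rnorm(100), 1L)
  p1 <- simulate_source_projection(tc, 5L, matrix(c(1, 0, 0), 1L), sm,
                                   sensor_noise_sd = 1, seed = 9L)
  p2 <- simulate_source_projection(tc, 5L, matrix(c(1, 0, 0), 1L), sm,
                                   sensor_noise_sd = 1, seed = 9L)
  expect_identical(p1$epochs$data, p2$epochs$data)
})

test_that("planted band effects have the stated direction in Welch band power", {
  pos <- fixture_grid_positions()
  spec <- band_effect_spec(list(alpha = c(8, 12)), list(alpha = 25:32),
                           list(alpha = 1.0), srate = 256, n_channels = 32L,
                           n_subjects = 30L, n_trials_per_condition = 6L,
                           trial_window = c(-0.5, 0.5), seed = 5L)
  subj <- simulate_band_trials(spec, pos)
  bd <- band_definition("alpha", 8, 12)
  diffs <- vapply(subj, function(s)
    mean(band_power_psd(s$A, bd)[25:32] - band_power_psd(s$B, bd)[25:32]),
    numeric(1))
  # with the effect size defined across subjects, the expected positive-sign
  # fraction at d = 1 is pnorm(1) ~ 0.84
  expect_gt(mean(diffs > 0), 0.7)
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 1e-3)
  # non-effect channels carry no systematic difference
  nul <- vapply(subj, function(s)
    mean(band_power_psd(s$A, bd)[1:8] - band_power_psd(s$B, bd)[1:8]),
    numeric(1))
  expect_gt(t.test(nul)$p.value, 0.01)
})

test_that("band trial generation validates its inputs", {
  expect_error(band_effect_spec(list(alpha = c(8, 12)), list(alpha = 1:2),
                                list(alpha = 0), srate = NaN, n_channels = 4L,
                                n_subjects = 2L, n_trials_per_condition = 2L),
               "srate")
  expect_error(band_effect_spec(list(alpha = c(12, 8)), list(alpha = 1:2),
                                list(alpha = 0), srate = 256, n_channels = 4L,
                                n_subjects = 2L, n_trials_per_condition = 2L))
})

test_that("noiseless single-source projection yields rank-1 sensor data", {
  sm <- synthetic_source_model(seed = 2L)
  tc <- matrix(sin(seq(0, 20, length.out = 200L)), 1L)
  proj <- simulate_source_projection(tc, 17L, matrix(c(0, 1, 0), 1L), sm,
                                     sensor_noise_sd = 0)
  expect_equal(qr(proj$epochs$data[1L, , ])$rank, 1L)
  expect_error(simulate_source_projection(tc, 10^6L, matrix(c(0, 1, 0), 1L), sm),
               "out of grid")
})

test_that("behavioral scores reach the target correlation and reject bad input", {
  set.seed(1)
  summ <- rnorm(79L)
  expect_error(simulate_behavior(summ, 1.0), "r_target")
  expect_error(simulate_behavior(rep(1, 10L), 0.5), "zero variance")
  r0 <- vapply(1:20, function(s)
    cor(summ, simulate_behavior(summ, 0, seed = s)), numeric(1))
  expect_lt(max(abs(r0)), 2.5 / sqrt(79))
  r9 <- vapply(1:20, function(s)
    cor(summ, simulate_behavior(summ, 0.9, seed = 100L + s)), numeric(1))
  expect_gt(mean(r9 >= 0.8 & r9 <= 0.96), 0.9)
})

test_that("epoched data round-trips losslessly through the container", {
  dat <- array(rnorm(2L * 3L * 7L) * 10^sample(-4:4, 42L, TRUE), c(2L, 3L, 7L))
  ep <- epoched_data(dat, srate = 256, ch_pos = cbind(1:3, 4:6),
                     times = seq(-1, by = 1 / 256, length.out = 7L),
                     condition = c("A", "B"))
  path <- file.path(tempdir(), "epochs_roundtrip")
  write_epochs(ep, path)
  back <- read_epochs(path)
  expect_identical(back$data, ep$data)
  expect_identical(back$times, ep$times)
  expect_equal(back$ch_pos, ep$ch_pos, ignore_attr = TRUE)
  expect_identical(back$condition, ep$condition)
  unlink(path, recursive = TRUE)
})
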