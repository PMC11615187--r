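## Core estimator: single-hidden-layer network fit to the nMVAR model,
## with Taylor-based separation into linear and nonlinear directed
## connectivity and time-shifted surrogate significance.

as_tc_array <- function(x) {
  # canonical cluster time-course layout: [M nodes, samples, trials]
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

#' Build the lagged regression dataset from cluster time courses
#'
#' Per trial, rows `(x(n); x_p)` for `n = p+1 ... T` are formed and pooled
#' across trials (no row spans a trial boundary). The design columns are
#' ordered node-major: for node j, lags d = 1..p occupy columns
#' `(j-1) p + d`. Every design and target column is standardized to mean 0,
#' SD 1 by its own pooled statistics.
#'
#' @param cluster_tcs Array `[M, samples, trials]` (or `M x samples` matrix).
#' @param p Lag order.
#' @return Object of class `lagged_dataset`: `X` `[n_obs, M p]`, `Y`
#'   `[n_obs, M]`, `M`, `p`, `trial` (row-to-trial map), centers and scales.
#' @export
build_lagged_dataset <- function(cluster_tcs, p) {
  x <- as_tc_array(cluster_tcs)
  M <- dim(x)[1L]; Tn <- dim(x)[2L]; ntr <- dim(x)[3L]
  stopifnot(p >= 1L)
  Xs <- list(); Ys <- list(); trial <- integer()
  for (tr in seq_len(ntr)) {
    if (Tn < p + 1L) {
      warning(sprintf("trial %d shorter than p+1 samples; skipped", tr))
      next
    }
    xt <- matrix(x[, , tr], M, Tn)
    idx <- (p + 1L):Tn
    Yt <- t(xt[, idx, drop = FALSE])
    Xt <- matrix(0, length(idx), M * p)
    for (j in seq_len(M))
      for (d in seq_len(p))
        Xt[, (j - 1L) * p + d] <- xt[j, idx - d]
    Xs[[length(Xs) + 1L]] <- Xt
    Ys[[length(Ys) + 1L]] <- Yt
    trial <- c(trial, rep(tr, length(idx)))
  }
  if (!length(Xs)) stop("no trial long enough for the requested lag order")
  X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
  xc <- colMeans(X); xs <- apply(X, 2L, sd)
  yc <- colMeans(Y); ys <- apply(Y, 2L, sd)
  if (any(xs == 0) || any(ys == 0))
    stop("constant series: zero variance under standardization")
  X <- sweep(sweep(X, 2L, xc), 2L, xs, "/")
  Y <- sweep(sweep(Y, 2L, yc), 2L, ys, "/")
  structure(list(X = X, Y = Y, M = M, p = p, trial = trial,
                 x_center = xc, x_scale = xs, y_center = yc, y_scale = ys),
            class = "lagged_dataset")
}

# OLS fit of the linear VAR on a lagged dataset; returns coefficients in the
# same node-major column layout [M targets x (M p)] plus residual metrics
ols_var_fit <- function(data, rows = NULL) {
  rows <- rows %||% seq_len(nrow(data$X))
  X <- data$X[rows, , drop = FALSE]; Y <- data$Y[rows, , drop = FALSE]
  B <- tryCatch(qr.solve(X, Y), error = function(e)
    stop("ill-conditioned design in VAR fit: ", conditionMessage(e)))
  R <- Y - X %*% B
  list(A = t(B), resid = R, sigma = crossprod(R) / nrow(R),
       mse = mean(R^2))
}

#' Linear VAR model-order selection by AIC and BIC
#'
#' Fits ordinary-least-squares linear VAR models for `p = 1 ... p_max` on a
#' common effective sample (the first `p_max` samples of every trial are
#' excluded for all candidate orders) and evaluates
#' `AIC = ln det(Sigma) + 2 p M^2 / n` and
#' `BIC = ln det(Sigma) + p M^2 ln(n) / n`.
#'
#' @param cluster_tcs Array `[M, samples, trials]`.
#' @param p_max Largest candidate order.
#' @return List: `aic`, `bic` (per order), `p_aic`, `p_bic`, and `p`
#'   (consensus: the smaller of the two argmins).
#' @export
select_model_order <- function(cluster_tcs, p_max) {
  x <- as_tc_array(cluster_tcs)
  stopifnot(p_max >= 1L)
  full <- build_lagged_dataset(x, p_max)
  n <- nrow(full$X); M <- full$M
  aic <- bic <- numeric(p_max)
  for (p in seq_len(p_max)) {
    cols <- as.vector(vapply(seq_len(M), function(j) (j - 1L) * as.integer(p_max) + seq_len(p),
                             integer(p)))
    sub <- full
    sub$X <- full$X[, cols, drop = FALSE]
    fit <- ols_var_fit(sub)
    ld <- determinant(fit$sigma, logarithm = TRUE)$modulus
    aic[p] <- ld + 2 * p * M^2 / n
    bic[p] <- ld + p * M^2 * log(n) / n
  }
  p_aic <- which.min(aic); p_bic <- which.min(bic)
  list(aic = aic, bic = bic, p_aic = p_aic, p_bic = p_bic,
       p = min(p_aic, p_bic))
}

mlp_predict <- function(W1, b1, W2, b2, X) {
  A1 <- tanh(X %*% t(W1) + matrix(b1, nrow(X), length(b1), byrow = TRUE))
  A1 %*% t(W2) + matrix(b2, nrow(X), length(b2), byrow = TRUE)
}

#' Train the nMVAR network (repeated 80/10/10 folds)
#'
#' For each fold a fresh random permutation splits the rows into 80%
#' training, 10% validation and 10% test. Weights are initialized uniformly
#' in `[-0.5, 0.5]` and updated in incremental (per-pattern) mode by
#' gradient descent with momentum and an adaptive learning rate (grown by
#' `lr_inc` after an epoch that lowers the training error, shrunk by
#' `lr_dec` with the epoch's update rejected when the error grows by more
#' than `err_ratio`). Early stopping keeps the weights with the best
#' validation error and halts after `patience` epochs without improvement.
#'
#' @param data A [build_lagged_dataset()] result.
#' @param H Hidden neurons (default 10).
#' @param folds Number of repeated random splits (default 10).
#' @param momentum,lr0 Momentum and initial learning rate.
#' @param max_epochs,patience Epoch cap and early-stopping patience.
#' @param lr_inc,lr_dec,err_ratio Adaptive-rate schedule constants.
#' @param seed Integer seed (fold substreams are derived from it).
#' @return Object of class `ncreann_model_set`: per-fold weights, index
#'   partitions and train/test MSE and R-squared.
#' @export
train_network <- function(data, H = 10L, folds = 10L, momentum = 0.9,
                          lr0 = 0.01, max_epochs = 200L, patience = 6L,
                          lr_inc = 1.05, lr_dec = 0.7, err_ratio = 1.04,
                          seed = 1L) {
  stopifnot(inherits(data, "lagged_dataset"), H >= 1L, folds >= 1L)
  n <- nrow(data$X); K <- ncol(data$X); M <- data$M
  if (n < 10 * (M * data$p * H) / folds)
    warning("few observations relative to network size; fits may be unstable")
  fold_fit <- function(f) {
    set.seed(substream_seed(seed, 606L, f))
    perm <- sample.int(n)
    n_te <- max(1L, floor(0.1 * n)); n_va <- n_te
    idx_te <- perm[seq_len(n_te)]
    idx_va <- perm[n_te + seq_len(n_va)]
    idx_tr <- perm[(n_te + n_va + 1L):n]
    W1 <- matrix(runif(H * K, -0.5, 0.5), H, K)
    b1 <- runif(H, -0.5, 0.5)
    W2 <- matrix(runif(M * H, -0.5, 0.5), M, H)
    b2 <- runif(M, -0.5, 0.5)
    ord <- sample.int(length(idx_tr)) - 1L
    fit <- train_mlp_cpp(data$X, data$Y, W1, b1, W2, b2,
                         idx_tr - 1L, idx_va - 1L, ord,
                         lr0, momentum, as.integer(max_epochs),
                         as.integer(patience), lr_inc, lr_dec, err_ratio)
    m_tr <- validate_model(fit, data, idx_tr)
    m_te <- validate_model(fit, data, idx_te)
    list(W1 = fit$W1, b1 = as.vector(fit$b1), W2 = fit$W2,
         b2 = as.vector(fit$b2), idx_train = idx_tr, idx_val = idx_va,
         idx_test = idx_te, epochs = fit$epochs,
         mse_train = m_tr$mse, r2_train = m_tr$r2,
         mse_test = m_te$mse, r2_test = m_te$r2)
  }
  fits <- lapply(seq_len(folds), fold_fit)
  structure(list(folds = fits, H = H, M = M, p = data$p,
                 hyper = list(momentum = momentum, lr0 = lr0,
                              max_epochs = max_epochs, patience = patience,
                              lr_inc = lr_inc, lr_dec = lr_dec,
                              err_ratio = err_ratio),
                 seed = seed),
            class = "ncreann_model_set")
}

#' Prediction error metrics on a data partition
#'
#' MSE is the squared residual pooled over nodes and rows; R-squared is
#' `1 - SS_res / SS_tot` pooled over nodes, with totals around the
#' partition's own node means.
#'
#' @param model A fold entry (list with `W1`, `b1`, `W2`, `b2`).
#' @param data A `lagged_dataset`.
#' @param rows Row indices of the partition.
#' @return List with `mse` and `r2`.
#' @export
validate_model <- function(model, data, rows) {
  if (!length(rows)) stop("empty partition")
  X <- data$X[rows, , drop = FALSE]; Y <- data$Y[rows, , drop = FALSE]
  if (any(apply(Y, 2L, sd) == 0)) stop("zero-variance targets in partition")
  E <- Y - mlp_predict(model$W1, model$b1, model$W2, model$b2, X)
  ss_tot <- sum(sweep(Y, 2L, colMeans(Y))^2)
  list(mse = mean(E^2), r2 = 1 - sum(E^2) / ss_tot)
}

# first-order Taylor coefficient matrix of the network at x = 0:
# A = W2 diag(g'(b1)) W1, with g = tanh
taylor_linear_map <- function(model) {
  model$W2 %*% (model$W1 * (1 - tanh(model$b1)^2))
}

split_lag_stack <- function(A, M, p) {
  lapply(seq_len(p), function(d) A[, (seq_len(M) - 1L) * p + d, drop = FALSE])
}

#' Linear directed connectivity from a trained network
#'
#' The network's map is linearized at the expansion point x = 0 (inputs are
#' standardized), giving lag matrices `A_d`; linear connectivity from source
#' i to target j is the mean absolute coefficient of i's lags in j's
#' equation. Convention: `lC[j, i]` stores the edge i -> j (row = target,
#' column = source).
#'
#' @param model A fold entry or an `ncreann_model_set` (fold-averaged).
#' @param M,p Node count and lag order (taken from the set when given one).
#' @return List: `lC` (M x M, nonnegative) and `A` (list of p `A_d`
#'   matrices, `A[[d]][j, i]` = linear weight of `x_i(n-d)` in `x_j(n)`).
#' @export
extract_linear_connectivity <- function(model, M = NULL, p = NULL) {
  if (inherits(model, "ncreann_model_set")) {
    parts <- lapply(model$folds, extract_linear_connectivity,
                    M = model$M, p = model$p)
    lC <- Reduce(`+`, lapply(parts, `[[`, "lC")) / length(parts)
    A <- lapply(seq_len(model$p), function(d)
      Reduce(`+`, lapply(parts, function(x) x$A[[d]])) / length(parts))
    return(list(lC = lC, A = A))
  }
  stopifnot(!is.null(M), !is.null(p))
  Afull <- taylor_linear_map(model)
  A <- split_lag_stack(Afull, M, p)
  lC <- Reduce(`+`, lapply(A, abs)) / p
  list(lC = lC, A = A)
}

#' Nonlinear directed connectivity from a trained network
#'
#' For source i, a restricted prediction lets node i act only through the
#' linear part of the map while every other node acts fully:
#' `y_restricted = f(x_tilde) + A (x - x_tilde)` where `x_tilde` zeroes the
#' p lag columns of node i (the expansion point of the Taylor split).
#' `NC[j, i] = ln(MSE_j(restricted i) / MSE_j(full))` on the evaluation
#' rows: positive when removing i's nonlinear contribution worsens the
#' prediction of j.
#'
#' @param model A fold entry (weights) or `ncreann_model_set`
#'   (test-partition fold average).
#' @param data A `lagged_dataset`.
#' @param rows Evaluation rows (required for a single fold entry).
#' @return Matrix `NC` (M x M, `[target, source]`).
#' @export
extract_nonlinear_connectivity <- function(model, data, rows = NULL) {
  if (inherits(model, "ncreann_model_set")) {
    ncs <- lapply(model$folds, function(f)
      extract_nonlinear_connectivity(f, data, f$idx_test))
    return(Reduce(`+`, ncs) / length(ncs))
  }
  stopifnot(inherits(data, "lagged_dataset"), !is.null(rows))
  M <- data$M; p <- data$p
  X <- data$X[rows, , drop = FALSE]; Y <- data$Y[rows, , drop = FALSE]
  Afull <- taylor_linear_map(model)
  pred_full <- mlp_predict(model$W1, model$b1, model$W2, model$b2, X)
  mse_full <- colMeans((Y - pred_full)^2)
  if (any(mse_full == 0)) stop("degenerate perfect fit: zero full MSE")
  NC <- matrix(0, M, M)
  for (i in seq_len(M)) {
    cols <- (i - 1L) * p + seq_len(p)
    Xt <- X
    Xt[, cols] <- 0
    pred_r <- mlp_predict(model$W1, model$b1, model$W2, model$b2, Xt) +
      X[, cols, drop = FALSE] %*% t(Afull[, cols, drop = FALSE])
    NC[, i] <- log(colMeans((Y - pred_r)^2) / mse_full)
  }
  NC
}

#' Fit the full nCREANN estimator on cluster time courses
#'
#' Builds the lagged dataset, trains the network over repeated folds, and
#' extracts fold-averaged linear and nonlinear connectivity (the nonlinear
#' log-ratio is evaluated on each fold's held-out test rows).
#'
#' @inheritParams train_network
#' @param cluster_tcs Array `[M, samples, trials]`.
#' @param p Lag order.
#' @param ... Passed to [train_network()].
#' @return Object of class `connectivity_result`: `lC`, `NC` (both M x M,
#'   `[target, source]`, self-connections on the diagonal), `A` (lag
#'   stack), per-fold `mse_train`, `mse_test`, `r2_train`, `r2_test`, and
#'   the fitted `models`.
#' @export
ncreann_fit <- function(cluster_tcs, p, H = 10L, folds = 10L, seed = 1L, ...) {
  data <- build_lagged_dataset(cluster_tcs, p)
  models <- train_network(data, H = H, folds = folds, seed = seed, ...)
  lin <- extract_linear_connectivity(models)
  NC <- extract_nonlinear_connectivity(models, data)
  structure(list(lC = lin$lC, NC = NC, A = lin$A, M = data$M, p = p,
                 mse_train = vapply(models$folds, `[[`, numeric(1), "mse_train"),
                 mse_test = vapply(models$folds, `[[`, numeric(1), "mse_test"),
                 r2_train = vapply(models$folds, `[[`, numeric(1), "r2_train"),
                 r2_test = vapply(models$folds, `[[`, numeric(1), "r2_test"),
                 models = models,
                 convention = "matrix[j, i] stores the directed edge i -> j (row = target, column = source); diagonal = self-connections"),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> M = %d nodes, p = %d lags, %d folds\n",
              x$M, x$p, length(x$mse_test)))
  cat(sprintf("  R2(train) %.4f  R2(test) %.4f  MSE(test) %.4g\n",
              mean(x$r2_train), mean(x$r2_test), mean(x$mse_test)))
  cat("  ", x$convention, "\n")
  invisible(x)
}

# circular shift of one node's samples within each trial by a per-(node,
# trial) uniform offset in [0.1 T, 0.9 T]; destroys cross-signal timing
# while preserving each series' internal dynamics
time_shift_surrogate <- function(tcs, seed) {
  x <- as_tc_array(tcs)
  M <- dim(x)[1L]; Tn <- dim(x)[2L]; ntr <- dim(x)[3L]
  set.seed(seed)
  for (tr in seq_len(ntr)) {
    for (j in seq_len(M)) {
      s <- sample(floor(0.1 * Tn):ceiling(0.9 * Tn), 1L)
      x[j, , tr] <- x[j, c((s + 1L):Tn, 1L:s), tr]
    }
  }
  x
}

#' Time-shifted surrogate significance of connectivity estimates
#'
#' Each surrogate dataset applies an independent circular time shift per
#' node and trial (offset uniform in `[0.1 T, 0.9 T]`), then the full
#' fit-and-extract pipeline is re-run with the same configuration. The
#' per-edge one-sided threshold is the 95th percentile of the surrogate
#' values; an edge is significant when the real estimate exceeds it.
#'
#' @inheritParams ncreann_fit
#' @param n_surrogates Number of surrogate datasets (default 100; a warning
#'   is issued below 20, where the quantile is unstable).
#' @param estimate Optional precomputed `connectivity_result` for the real
#'   data (it is computed here when missing).
#' @return List: `estimate`, `lc_threshold`, `nc_threshold`,
#'   `lc_significant`, `nc_significant` (logical M x M), and the surrogate
#'   value arrays `[M, M, n_surrogates]`.
#' @export
surrogate_significance <- function(cluster_tcs, p, H = 10L, folds = 10L,
                                   n_surrogates = 100L, seed = 1L,
                                   estimate = NULL, ...) {
  if (n_surrogates < 20L)
    warning("fewer than 20 surrogates: the 95th-percentile threshold is unstable")
  tcs <- as_tc_array(cluster_tcs)
  if (is.null(estimate))
    estimate <- ncreann_fit(tcs, p, H = H, folds = folds, seed = seed, ...)
  M <- estimate$M
  lc_s <- array(0, dim = c(M, M, n_surrogates))
  nc_s <- array(0, dim = c(M, M, n_surrogates))
  for (s in seq_len(n_surrogates)) {
    sur <- time_shift_surrogate(tcs, substream_seed(seed, 707L, s))
    fit <- ncreann_fit(sur, p, H = H, folds = folds,
                       seed = substream_seed(seed, 708L, s), ...)
    lc_s[, , s] <- fit$lC
    nc_s[, , s] <- fit$NC
  }
  lc_thr <- apply(lc_s, c(1L, 2L), quantile, probs = 0.95, names = FALSE)
  nc_thr <- apply(nc_s, c(1L, 2L), quantile, probs = 0.95, names = FALSE)
  list(estimate = estimate,
       lc_threshold = lc_thr, nc_threshold = nc_thr,
       lc_significant = estimate$lC > lc_thr,
       nc_significant = estimate$NC > nc_thr,
       lc_surrogates = lc_s, nc_surrogates = nc_s)
}
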