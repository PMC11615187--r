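## End-to-end synthetic connectivity study: two paired conditions whose
## difference in network-mean linear connectivity is planted with a known
## across-subject effect size.

# companion matrix of a VAR coefficient stack
var_companion <- function(A) {
  M <- nrow(A[[1L]]); p <- length(A)
  Cm <- matrix(0, M * p, M * p)
  for (d in seq_len(p)) Cm[seq_len(M), (d - 1L) * M + seq_len(M)] <- A[[d]]
  if (p > 1L) Cm[M + seq_len(M * (p - 1L)), seq_len(M * (p - 1L))] <- diag(M * (p - 1L))
  Cm
}

# per-node innovation variances q giving unit stationary variance on every
# node: the stationary covariance is linear in q, so q solves a small linear
# system (one Lyapunov solve per node)
unit_variance_noise <- function(A) {
  M <- nrow(A[[1L]]); p <- length(A)
  Cm <- var_companion(A)
  S <- solve(diag((M * p)^2) - kronecker(Cm, Cm))
  B <- matrix(0, M, M)
  for (j in seq_len(M)) {
    Q <- matrix(0, M * p, M * p)
    Q[j, j] <- 1
    B[, j] <- matrix(S %*% as.vector(Q), M * p)[cbind(seq_len(M), seq_len(M))]
  }
  q <- solve(B, rep(1, M))
  if (any(q <= 0))
    stop("couplings too strong for unit-variance normalization")
  q
}

#' Simulate a two-condition multi-subject connectivity study
#'
#' Every subject carries the same acyclic 3-node VAR(2) wiring. Per-node
#' innovation variances are chosen so each node has unit stationary
#' variance, which makes the standardized coefficients (the scale the
#' estimator works on) equal the generating ones; the network-mean linear
#' connectivity is then exactly linear in the coupling scale, and the
#' condition effect can be planted in closed form. Per-subject
#' condition differences (A minus B) of the true network mean are drawn as
#' `N(effect_d * s0, s0)` with `s0 = spread * L0` (L0 = baseline network
#' mean), so their across-subject Cohen's d equals `effect_d` in
#' population. The default `spread = 0.5` matches the ~50% between-subject
#' coefficient of variation typical of such connectivity estimates. Both
#' conditions of a subject share innovation noise (common random numbers),
#' the paired-design choice that lets the planted within-subject difference
#' dominate estimation noise.
#'
#' @param n_subjects Number of subjects (default 40).
#' @param effect_d Planted condition effect size (Cohen's d of the
#'   per-subject true connectivity difference; default 0.5).
#' @param spread Between-subject SD of the difference as a fraction of the
#'   baseline network mean (default 0.5).
#' @param n_samples,n_trials Samples per trial and trials per condition.
#' @param seed Integer seed (per-subject substreams).
#' @return List with `subjects` (each with `tcs_A`, `tcs_B` arrays
#'   `[3, n_samples, n_trials]`, the planted `delta` and coupling scales),
#'   `M`, `p`, `baseline_lc`, and the coupling template.
#' @export
simulate_connectivity_study <- function(n_subjects = 40L, effect_d = 0.5,
                                        spread = 0.5, n_samples = 384L,
                                        n_trials = 10L, seed = 1L) {
  M <- 3L; p <- 2L
  base_A <- function(cpl) {
    A1 <- diag(c(0.3, 0.25, 0.2)); A2 <- diag(0.05, M)
    A1[2L, 1L] <- 0.18 * cpl
    A1[3L, 1L] <- 0.15 * cpl
    A1[3L, 2L] <- 0.12 * cpl
    A2[2L, 1L] <- 0.08 * cpl
    list(A1, A2)
  }
  # network mean of the lag-averaged |couplings|: linear in the scale
  slope <- (0.18 + 0.08 + 0.15 + 0.12) / 2 / (M * (M - 1L))
  L0 <- slope * 1
  s0 <- spread * L0
  set.seed(substream_seed(seed, 909L, 1L))
  deltas <- rnorm(n_subjects, mean = effect_d * s0, sd = s0)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    cA <- max((L0 + deltas[s] / 2) / slope, 0)
    cB <- max((L0 - deltas[s] / 2) / slope, 0)
    make <- function(cpl) {
      A <- base_A(cpl)
      # shared seed across conditions: common innovations per subject
      spec <- nmvar_spec(M, p, A, noise_sd = sqrt(unit_variance_noise(A)),
                         n_samples = n_samples, n_trials = n_trials,
                         seed = substream_seed(seed, 910L, s))
      nmvar_tcs(simulate_nmvar(spec))
    }
    list(tcs_A = make(cA), tcs_B = make(cB), delta = deltas[s],
         c_A = cA, c_B = cB)
  })
  list(subjects = subjects, M = M, p = p, effect_d = effect_d,
       baseline_lc = L0, spread = spread, template = base_A(1), seed = seed)
}

#' Fit the connectivity estimator to every subject of a simulated study
#'
#' @param study A [simulate_connectivity_study()] result.
#' @param p Lag order used for fitting (defaults to the study's true order).
#' @param H,folds,seed,... Passed to [ncreann_fit()].
#' @return List of arrays `[subjects, M, M]`: `lc_A`, `lc_B`, `nc_A`,
#'   `nc_B`, plus `r2_test` `[subjects, 2]`.
#' @export
fit_connectivity_study <- function(study, p = study$p, H = 10L, folds = 3L,
                                   seed = 1L, ...) {
  ns <- length(study$subjects); M <- study$M
  lc_A <- lc_B <- nc_A <- nc_B <- array(0, dim = c(ns, M, M))
  r2 <- matrix(0, ns, 2L)
  for (s in seq_len(ns)) {
    # same fit seed for both conditions: with common innovations in the
    # generator, matched splits/initialization keep estimation errors paired
    fa <- ncreann_fit(study$subjects[[s]]$tcs_A, p, H = H, folds = folds,
                      seed = substream_seed(seed, 911L, s), ...)
    fb <- ncreann_fit(study$subjects[[s]]$tcs_B, p, H = H, folds = folds,
                      seed = substream_seed(seed, 911L, s), ...)
    lc_A[s, , ] <- fa$lC; lc_B[s, , ] <- fb$lC
    nc_A[s, , ] <- fa$NC; nc_B[s, , ] <- fb$NC
    r2[s, ] <- c(mean(fa$r2_test), mean(fb$r2_test))
  }
  list(lc_A = lc_A, lc_B = lc_B, nc_A = nc_A, nc_B = nc_B, r2_test = r2)
}
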