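# shared fixture builders (all generated in code, seeded)

# stable linear VAR(2), M = 3, with distinct coupling magnitudes
fixture_var2_A <- function(cpl = 1) {
  A1 <- diag(c(0.4, 0.3, 0.2))
  A1[2L, 1L] <- 0.5 * cpl
  A1[3L, 2L] <- 0.3 * cpl
  A1[1L, 3L] <- 0.15 * cpl
  A2 <- diag(0.1, 3L)
  A2[3L, 1L] <- 0.2 * cpl
  list(A1, A2)
}

# near-resonant VAR(2): most of each node's variance is linearly predictable
fixture_resonant_A <- function(r = 0.995, th = c(0.3, 0.5, 0.8), cpl = 0.05) {
  A1 <- diag(2 * r * cos(th))
  A2 <- diag(-r^2, 3L)
  A1[2L, 1L] <- cpl
  A1[3L, 2L] <- cpl
  list(A1, A2)
}

# 3-node system with a single square-type nonlinear edge 2 -> 3
fixture_nonlinear <- function(n_samples = 4000L, seed = 1L, gain = 0.6) {
  A <- list(matrix(0, 3L, 3L))
  diag(A[[1L]]) <- c(0.5, 0.5, 0.4)
  A[[1L]][2L, 1L] <- 0.4
  nl <- data.frame(target = 3L, source = 2L, lag = 1L, kind = "square",
                   gain = gain)
  nmvar_spec(3L, 1L, A, nl, noise_sd = 1, n_samples = n_samples, seed = seed)
}

# regular grid sensor layout
fixture_grid_positions <- function(nx = 8L, ny = 4L)
  cbind(rep(seq_len(nx), each = ny), rep(seq_len(ny), nx))

offdiag_idx <- function(M) which(diag(M) == 0)
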