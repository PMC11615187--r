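#' Specify a ground-truth nonlinear MVAR system
#'
#' Defines an M-node order-p nonlinear multivariate autoregressive system
#' x(n) = sum_d A_d x(n-d) + f_nl(past) + e(n) with Gaussian i.i.d. residuals.
#' The nonlinear term library is fixed to squares, tanh-saturations and
#' pairwise cross-products of lagged values: a span of smooth and polynomial
#' nonlinearities against which a Taylor-based estimator can be validated.
#'
#' @param M Node count.
#' @param p Lag order (>= 1).
#' @param A List of p M x M matrices of linear coefficients; `A[[d]][i, j]` is
#'   the contribution of node j at lag d to node i ("a_ij^d").
#' @param nonlinear_terms Optional data frame with columns `target`, `source`,
#'   `lag`, `kind` (one of `"square"`, `"tanh"`, `"cross"`), `gain`, and for
#'   `"cross"` additionally `source2`, `lag2`: the term
#'   `gain * x_source(n-lag) * x_source2(n-lag2)`.
#' @param noise_sd Residual standard deviation, scalar or length-M.
#' @param n_samples Retained samples per trial (after burn-in).
#' @param n_trials Number of independently generated trials.
#' @param seed Integer seed; trials use counter-based substreams.
#' @return An object of class `nmvar_spec`.
#' @export
nmvar_spec <- function(M, p, A, nonlinear_terms = NULL, noise_sd = 1,
                       n_samples = 1000L, n_trials = 1L, seed = 1L) {
  stopifnot(M >= 1L, p >= 1L, is.list(A), length(A) == p)
  for (Ad in A) stopifnot(is.matrix(Ad), all(dim(Ad) == c(M, M)), all(is.finite(Ad)))
  rho <- companion_spectral_radius(A)
  if (rho >= 1)
    stop(sprintf("linear part is non-stationary: companion spectral radius %.3f >= 1", rho))
  if (!is.null(nonlinear_terms)) {
    nonlinear_terms <- as.data.frame(nonlinear_terms)
    need <- c("target", "source", "lag", "kind", "gain")
    stopifnot(all(need %in% names(nonlinear_terms)))
    stopifnot(all(nonlinear_terms$kind %in% c("square", "tanh", "cross")),
              all(is.finite(nonlinear_terms$gain)),
              all(nonlinear_terms$target %in% seq_len(M)),
              all(nonlinear_terms$source %in% seq_len(M)),
              all(nonlinear_terms$lag >= 1L), all(nonlinear_terms$lag <= p))
    if (any(nonlinear_terms$kind == "cross")) {
      stopifnot(all(c("source2", "lag2") %in% names(nonlinear_terms)))
      cr <- nonlinear_terms$kind == "cross"
      stopifnot(all(nonlinear_terms$source2[cr] %in% seq_len(M)),
                all(nonlinear_terms$lag2[cr] >= 1L),
                all(nonlinear_terms$lag2[cr] <= p))
    }
  }
  noise_sd <- rep_len(noise_sd, M)
  stopifnot(all(noise_sd >= 0), all(is.finite(noise_sd)))
  structure(list(M = M, p = p, A = A, nonlinear_terms = nonlinear_terms,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 spectral_radius = rho),
            class = "nmvar_spec")
}

#' Simulate a ground-truth nMVAR system
#'
#' Each trial is generated independently from zero initial conditions with a
#' burn-in of `max(10 p, 100)` samples discarded before retention.
#'
#' @param spec An [nmvar_spec].
#' @return List with `data` (array `[trials, M, n_samples]`), `edges` (data
#'   frame `from`, `to`, `type` in {"linear","nonlinear"} listing every
#'   planted directed edge), and `spec`.
#' @export
simulate_nmvar <- function(spec) {
  stopifnot(inherits(spec, "nmvar_spec"))
  M <- spec$M; p <- spec$p; burn <- max(10L * p, 100L)
  total <- spec$n_samples + burn + p
  out <- array(0, dim = c(spec$n_trials, M, spec$n_samples))
  nl <- spec$nonlinear_terms
  for (tr in seq_len(spec$n_trials)) {
    set.seed(substream_seed(spec$seed, 101L, tr))
    e <- matrix(rnorm(M * total), M, total) * spec$noise_sd
    x <- matrix(0, M, total)
    for (n in (p + 1L):total) {
      xn <- e[, n]
      for (d in seq_len(p)) xn <- xn + spec$A[[d]] %*% x[, n - d]
      if (!is.null(nl)) {
        for (k in seq_len(nrow(nl))) {
          u <- x[nl$source[k], n - nl$lag[k]]
          v <- switch(nl$kind[k],
                      square = u * u,
                      tanh   = tanh(u),
                      cross  = u * x[nl$source2[k], n - nl$lag2[k]])
          xn[nl$target[k]] <- xn[nl$target[k]] + nl$gain[k] * v
        }
      }
      x[, n] <- xn
    }
    if (!all(is.finite(x)))
      stop("simulation produced non-finite values; reduce nonlinear gains")
    out[tr, , ] <- x[, (burn + p + 1L):total, drop = FALSE]
  }
  edges <- data.frame(from = integer(), to = integer(), type = character())
  for (d in seq_len(p)) {
    nz <- which(spec$A[[d]] != 0 & row(spec$A[[d]]) != col(spec$A[[d]]), arr.ind = TRUE)
    if (nrow(nz))
      edges <- rbind(edges, data.frame(from = nz[, 2L], to = nz[, 1L],
                                       type = "linear"))
  }
  if (!is.null(nl) && nrow(nl))
    edges <- rbind(edges, data.frame(from = nl$source, to = nl$target,
                                     type = "nonlinear"))
  edges <- unique(edges)
  rownames(edges) <- NULL
  list(data = out, edges = edges, spec = spec)
}

#' Reshape a simulation into the connectivity time-course layout
#'
#' [simulate_nmvar()] returns `[trials, M, samples]` (the epoch layout);
#' the connectivity stage consumes `[M, samples, trials]` (the cluster
#' time-course layout). This converts between the two.
#'
#' @param sim A [simulate_nmvar()] result (or its `data` array).
#' @return Array `[M, samples, trials]`.
#' @export
nmvar_tcs <- function(sim) {
  x <- if (is.list(sim)) sim$data else sim
  stopifnot(is.array(x), length(dim(x)) == 3L)
  aperm(x, c(2L, 3L, 1L))
}

## -- band-limited two-condition sensor epochs --------------------------------

#' Specify planted two-condition band-power effects
#'
#' @param bands Named list of `c(f_lo, f_hi)` Hz pairs, e.g.
#'   `list(theta = c(4, 7), alpha = c(8, 12), beta = c(12, 25))`.
#' @param channel_groups Named list (same names as `bands`) of channel index
#'   vectors carrying each band's effect.
#' @param effect_size_d Named numeric (same names): between-condition Cohen's d
#'   of the planted band-amplitude difference across subjects (A minus B;
#'   negative flips direction).
#' @param srate Sampling rate in Hz.
#' @param n_channels Total channel count.
#' @param n_subjects,n_trials_per_condition Study size.
#' @param trial_window `c(t_min, t_max)` seconds.
#' @param seed Integer seed.
#' @export
band_effect_spec <- function(bands, channel_groups, effect_size_d, srate,
                             n_channels, n_subjects, n_trials_per_condition,
                             trial_window = c(-1, 1), seed = 1L) {
  if (!is.finite(srate) || srate <= 0) stop("srate must be finite and positive")
  stopifnot(is.list(bands), length(bands) >= 1L,
            setequal(names(bands), names(channel_groups)),
            setequal(names(bands), names(effect_size_d)))
  for (b in bands) stopifnot(length(b) == 2L, b[1L] < b[2L], b[2L] < srate / 2)
  for (g in channel_groups) stopifnot(all(g >= 1L), all(g <= n_channels))
  stopifnot(trial_window[1L] < trial_window[2L])
  structure(list(bands = bands, channel_groups = channel_groups,
                 effect_size_d = effect_size_d, srate = srate,
                 n_channels = as.integer(n_channels),
                 n_subjects = as.integer(n_subjects),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 trial_window = trial_window, seed = as.integer(seed)),
            class = "band_effect_spec")
}

# spectrally shaped Gaussian noise: `shape(f)` weights the amplitude spectrum;
# returned series has unit RMS
shaped_noise <- function(n, srate, shape) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * srate / n
  g <- shape(abs(f))
  g[1L] <- 0
  W <- W * g
  x <- Re(fft(W, inverse = TRUE)) / n
  x / max(sd(x), .Machine$double.eps)
}

one_over_f_noise <- function(n, srate)
  shaped_noise(n, srate, function(f) ifelse(f > 0, 1 / sqrt(pmax(f, 0.5)), 0))

narrowband_noise <- function(n, srate, f_lo, f_hi)
  shaped_noise(n, srate, function(f) as.numeric(f >= f_lo & f <= f_hi))

#' Simulate two-condition epoched sensor data with planted band effects
#'
#' Every channel carries 1/f background noise; effect channels additionally
#' carry narrowband (band-filtered noise) oscillatory activity whose amplitude
#' differs between conditions. Per-subject amplitude jitter is log-normal; the
#' per-subject condition difference is drawn so that its across-subject
#' Cohen's d equals `effect_size_d` in population.
#'
#' @param spec A [band_effect_spec].
#' @param channel_positions Matrix `[n_channels, 2 or 3]` of positions,
#'   forwarded into each [epoched_data] for adjacency construction downstream.
#' @return List of length `n_subjects`; each element has elements `A` and `B`
#'   ([epoched_data]) plus `truth` (per-band planted amplitudes).
#' @export
simulate_band_trials <- function(spec, channel_positions) {
  stopifnot(inherits(spec, "band_effect_spec"))
  channel_positions <- as.matrix(channel_positions)
  stopifnot(nrow(channel_positions) == spec$n_channels,
            all(is.finite(channel_positions)))
  ns <- round(diff(spec$trial_window) * spec$srate)
  times <- seq(spec$trial_window[1L], by = 1 / spec$srate, length.out = ns)
  bn <- names(spec$bands)
  # relative amplitude-difference scale: d is carried as mean/sd of the
  # per-subject fractional amplitude gap
  gamma <- 0.3
  lapply(seq_len(spec$n_subjects), function(s) {
    set.seed(substream_seed(spec$seed, 202L, s))
    amp0 <- exp(rnorm(length(bn), 0, 0.1)); names(amp0) <- bn
    gap <- stats::setNames(rnorm(length(bn),
                                 mean = gamma * unlist(spec$effect_size_d)[bn],
                                 sd = gamma), bn)
    amp <- list(A = pmax(amp0 * (1 + gap / 2), 0.02),
                B = pmax(amp0 * (1 - gap / 2), 0.02))
    make_cond <- function(cond) {
      dat <- array(0, dim = c(spec$n_trials_per_condition, spec$n_channels, ns))
      for (tr in seq_len(spec$n_trials_per_condition)) {
        for (ch in seq_len(spec$n_channels))
          dat[tr, ch, ] <- one_over_f_noise(ns, spec$srate)
        for (b in bn) {
          for (ch in spec$channel_groups[[b]]) {
            dat[tr, ch, ] <- dat[tr, ch, ] + amp[[cond]][b] *
              narrowband_noise(ns, spec$srate, spec$bands[[b]][1L], spec$bands[[b]][2L])
          }
        }
      }
      epoched_data(dat, srate = spec$srate, ch_pos = channel_positions,
                   times = times, condition = rep(cond, spec$n_trials_per_condition))
    }
    list(A = make_cond("A"), B = make_cond("B"), truth = amp)
  })
}

## -- leadfield projection -----------------------------------------------------

#' Source model (leadfield + voxel grid + atlas labels)
#'
#' @param leadfield Array `[channels, voxels, 3]`: sensor gain of a unit dipole
#'   at each voxel along x/y/z.
#' @param coords Matrix `[voxels, 3]` of voxel centers in mm.
#' @param edge_mm Voxel edge length in mm.
#' @param labels Integer atlas label per voxel (0 / NA = unlabeled).
#' @export
source_model <- function(leadfield, coords, edge_mm, labels) {
  stopifnot(is.array(leadfield), length(dim(leadfield)) == 3L,
            dim(leadfield)[3L] == 3L)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == dim(leadfield)[2L], ncol(coords) == 3L,
            edge_mm > 0, length(labels) == nrow(coords))
  structure(list(leadfield = leadfield, coords = coords,
                 edge_mm = edge_mm, labels = as.integer(labels)),
            class = "source_model")
}

#' Project planted source time courses to the sensors
#'
#' @param source_tcs Matrix `[K, samples]` or array `[K, samples, trials]` of
#'   source activity.
#' @param source_voxels Integer voxel index per source.
#' @param source_orients Matrix `[K, 3]` of dipole orientations (normalized
#'   internally).
#' @param model A [source_model].
#' @param sensor_noise_sd White sensor noise SD.
#' @param srate Sampling rate for the returned container.
#' @param seed Integer seed for the noise.
#' @return List: `epochs` ([epoched_data]) and `truth` (voxel indices and
#'   orientations of the planted sources).
#' @export
simulate_source_projection <- function(source_tcs, source_voxels, source_orients,
                                       model, sensor_noise_sd = 0, srate = 256,
                                       seed = 1L) {
  stopifnot(inherits(model, "source_model"))
  V <- dim(model$leadfield)[2L]
  if (any(source_voxels < 1L) || any(source_voxels > V))
    stop("source voxel index out of grid")
  if (length(dim(source_tcs) %||% 0) < 3L)
    source_tcs <- array(as.matrix(source_tcs),
                        dim = c(nrow(as.matrix(source_tcs)),
                                ncol(as.matrix(source_tcs)), 1L))
  K <- dim(source_tcs)[1L]; ns <- dim(source_tcs)[2L]; ntr <- dim(source_tcs)[3L]
  source_orients <- as.matrix(source_orients)
  stopifnot(nrow(source_orients) == K, length(source_voxels) == K)
  source_orients <- source_orients / sqrt(rowSums(source_orients^2))
  C <- dim(model$leadfield)[1L]
  gains <- vapply(seq_len(K), function(k)
    model$leadfield[, source_voxels[k], ] %*% source_orients[k, ],
    numeric(C))                       # C x K
  dat <- array(0, dim = c(ntr, C, ns))
  set.seed(substream_seed(seed, 303L, 1L))
  for (tr in seq_len(ntr)) {
    s <- matrix(source_tcs[, , tr], K, ns)
    dat[tr, , ] <- gains %*% s +
      if (sensor_noise_sd > 0) matrix(rnorm(C * ns, sd = sensor_noise_sd), C, ns) else 0
  }
  list(epochs = epoched_data(dat, srate = srate),
       truth = list(voxels = source_voxels, orients = source_orients))
}

#' Generate behavioral scores correlated with a connectivity summary
#'
#' Scores are built as `r z(x) + sqrt(1 - r^2) e` with standard-normal `e`, so
#' the population correlation with the summary `x` equals `r_target`.
#'
#' @param summary Numeric vector (one connectivity summary per subject).
#' @param r_target Target population Pearson correlation, in (-1, 1).
#' @param seed Integer seed.
#' @return Numeric vector of scores, same length as `summary`.
#' @export
simulate_behavior <- function(summary, r_target, seed = 1L) {
  if (abs(r_target) >= 1) stop("|r_target| must be < 1")
  if (sd(summary) == 0) stop("summary vector has zero variance")
  z <- as.vector(scale(summary))
  set.seed(substream_seed(seed, 404L, 1L))
  r_target * z + sqrt(1 - r_target^2) * rnorm(length(z))
}
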