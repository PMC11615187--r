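#' Frequency band definition
#'
#' @param name Band label, e.g. `"theta"`.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(f_lo), is.finite(f_hi), 0 < f_lo, f_lo < f_hi)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' Canonical theta/alpha/beta band set
#'
#' Theta 4-7 Hz, alpha 8-12 Hz, beta 12-25 Hz.
#' @return Named list of [band_definition] objects.
#' @export
default_bands <- function() {
  list(theta = band_definition("theta", 4, 7),
       alpha = band_definition("alpha", 8, 12),
       beta  = band_definition("beta", 12, 25))
}

next_pow2 <- function(n) 2L^ceiling(log2(n))

# complex Morlet wavelet sampled at srate, unit L2 energy; Gaussian envelope
# SD sigma_t = n_cycles / (2 pi f)
morlet_wavelet <- function(f, srate, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * srate)
  t <- seq(-half, half) / srate
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet time-frequency decomposition of epoched data
#'
#' Computes the squared magnitude of the complex Morlet wavelet transform per
#' trial and averages over trials (induced and evoked power together; no
#' evoked subtraction). Time points where the wavelet support overruns the
#' epoch are marked `NA` (invalid edges), per frequency.
#'
#' @param epochs An [epoched_data] object.
#' @param freqs Frequencies in Hz (strictly increasing). Default 2-30 Hz in
#'   1 Hz steps.
#' @param n_cycles Wavelet width in cycles (Gaussian envelope SD
#'   `n_cycles / (2 pi f)`); default 5.
#' @return Object of class `tfr_power`: `power` array
#'   `[channels, freqs, times]` (trial-averaged, `NA` at invalid edges),
#'   `freqs`, `times`, `n_trials_averaged`.
#' @export
morlet_tfr <- function(epochs, freqs = 2:30, n_cycles = 5) {
  stopifnot(inherits(epochs, "epoched_data"), all(diff(freqs) > 0))
  srate <- epochs$srate
  if (max(freqs) >= srate / 2) stop("frequencies must be below Nyquist")
  ns <- dim(epochs$data)[3L]
  epoch_len <- ns / srate
  if (epoch_len < n_cycles / min(freqs))
    stop(sprintf("epoch too short (%.2f s) for %g cycles at %g Hz",
                 epoch_len, n_cycles, min(freqs)))
  nt <- dim(epochs$data)[1L]; nc <- dim(epochs$data)[2L]
  wl <- lapply(freqs, morlet_wavelet, srate = srate, n_cycles = n_cycles)
  halves <- vapply(wl, function(w) (length(w) - 1L) %/% 2L, integer(1))
  nfft <- next_pow2(ns + max(lengths(wl)) - 1L)
  # one FFT per (trial, channel) signal, reused across frequencies
  S <- matrix(0, nfft, nt * nc)
  for (tr in seq_len(nt))
    S[seq_len(ns), (tr - 1L) * nc + seq_len(nc)] <- t(epochs$data[tr, , , drop = TRUE])
  Sf <- stats::mvfft(S)
  pow <- array(0, dim = c(nc, length(freqs), ns))
  for (k in seq_along(freqs)) {
    Wf <- fft(c(wl[[k]], rep(0, nfft - length(wl[[k]]))))
    conv <- stats::mvfft(Sf * Wf, inverse = TRUE) / nfft
    # wavelet is centered at sample halves[k]+1 of its support
    seg <- Mod(conv[halves[k] + seq_len(ns), , drop = FALSE])^2
    for (tr in seq_len(nt))
      pow[, k, ] <- pow[, k, ] + t(seg[, (tr - 1L) * nc + seq_len(nc), drop = FALSE])
  }
  pow <- pow / nt
  for (k in seq_along(freqs)) {
    h <- halves[k]
    if (h > 0) pow[, k, c(seq_len(min(h, ns)), ns - seq_len(min(h, ns)) + 1L)] <- NA_real_
  }
  structure(list(power = pow, freqs = freqs, times = epochs$times,
                 ch_names = epochs$ch_names, n_trials_averaged = nt),
            class = "tfr_power")
}

#' Band-and-window average power per channel
#'
#' @param tfr A `tfr_power` object from [morlet_tfr()].
#' @param band A [band_definition].
#' @param window `c(t0, t1)` seconds; must lie within the valid (non-edge)
#'   time range of every selected frequency.
#' @return Numeric vector, one mean power per channel.
#' @export
band_power <- function(tfr, band, window) {
  stopifnot(inherits(tfr, "tfr_power"), inherits(band, "band_definition"))
  fi <- which(tfr$freqs >= band$f_lo & tfr$freqs <= band$f_hi)
  ti <- which(tfr$times >= window[1L] & tfr$times <= window[2L])
  if (!length(fi) || !length(ti)) stop("empty frequency or time selection")
  sel <- tfr$power[, fi, ti, drop = FALSE]
  if (anyNA(sel))
    stop("window overlaps wavelet edge region; choose a window inside the valid range")
  apply(sel, 1L, mean)
}

#' Periodogram-based band power per channel
#'
#' A fast spectral summary used for large simulation studies: per trial and
#' channel, the mean periodogram power over the band's frequency bins within
#' the window, averaged over trials. Agrees with the wavelet route in rank
#' order of channels; it has no time resolution.
#'
#' @inheritParams band_power
#' @param epochs An [epoched_data] object.
#' @return Numeric vector, one value per channel.
#' @export
band_power_psd <- function(epochs, band, window = range(epochs$times)) {
  stopifnot(inherits(epochs, "epoched_data"), inherits(band, "band_definition"))
  ti <- which(epochs$times >= window[1L] & epochs$times <= window[2L])
  if (length(ti) < 8L) stop("window selects too few samples")
  n <- length(ti)
  f <- seq(0, n - 1) * epochs$srate / n
  fi <- which(f >= band$f_lo & f <= band$f_hi & f <= epochs$srate / 2)
  if (!length(fi)) stop("band selects no frequency bins at this window length")
  nt <- dim(epochs$data)[1L]; nc <- dim(epochs$data)[2L]
  out <- numeric(nc)
  for (tr in seq_len(nt)) {
    X <- t(epochs$data[tr, , ti, drop = TRUE])       # n x channels
    X <- sweep(X, 2L, colMeans(X))
    P <- Mod(stats::mvfft(X))^2 / n
    out <- out + colMeans(P[fi, , drop = FALSE])
  }
  out / nt
}

#' Hamming-windowed sinc FIR band-pass filter
#'
#' Designs a linear-phase FIR band-pass (Hamming window; stop-band
#' attenuation ~53 dB) and applies it either zero-phase (forward-backward,
#' the default) or causally with group-delay compensation.
#'
#' @param series Numeric vector, matrix (one series per row), or
#'   [epoched_data] (filtered per trial and channel).
#' @param srate Sampling rate in Hz (taken from the object for
#'   [epoched_data]).
#' @param band A [band_definition].
#' @param transition_width Transition band in Hz; default
#'   `max(2, 0.25 * f_lo)` (Hamming design rule sets the order from it).
#' @param zero_phase If `TRUE` (default) apply forward-backward
#'   (`signal::filtfilt`); otherwise single-pass with the group delay removed.
#'   Zero-phase filtering is non-causal; see the package vignette for its
#'   implications for directed-connectivity estimates.
#' @return Filtered data, same shape as the input.
#' @export
bandpass_fir <- function(series, srate = NULL, band, transition_width = NULL,
                         zero_phase = TRUE) {
  if (inherits(series, "epoched_data")) {
    out <- series
    for (tr in seq_len(dim(series$data)[1L]))
      out$data[tr, , ] <- bandpass_fir(series$data[tr, , , drop = TRUE],
                                       series$srate, band, transition_width,
                                       zero_phase)
    return(out)
  }
  stopifnot(inherits(band, "band_definition"), is.finite(srate), srate > 0)
  if (band$f_hi >= srate / 2) stop("upper band edge at or above Nyquist")
  tw <- transition_width %||% max(2, 0.25 * band$f_lo)
  # Hamming design rule: order ~ 3.3 / normalized transition width
  ord <- ceiling(3.3 * srate / tw)
  ord <- ord + ord %% 2L                       # even order, type-I FIR
  h <- as.numeric(signal::fir1(ord, c(band$f_lo, band$f_hi) / (srate / 2),
                               type = "pass"))
  apply_one <- function(x) {
    if (length(x) <= 3L * ord)
      stop(sprintf("series too short (%d) for filter order %d", length(x), ord))
    if (zero_phase) {
      signal::filtfilt(h, 1, x)
    } else {
      y <- signal::filter(h, 1, c(x, numeric(ord / 2)))
      as.numeric(y[(ord / 2 + 1L):(length(x) + ord / 2)])
    }
  }
  if (is.matrix(series)) t(apply(series, 1L, apply_one)) else apply_one(series)
}
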