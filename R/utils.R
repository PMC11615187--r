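#' @useDynLib ncreann, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor quantile var fft t.test cor.test pt qt
#' @importFrom utils write.csv read.csv
NULL

#' Derive a reproducible substream seed
#'
#' Expands one global integer seed into independent substream seeds by a
#' counter-based integer hash, so that per-subject / per-trial / per-surrogate
#' generation is reproducible regardless of the order in which substreams are
#' consumed.
#'
#' @param seed Global integer seed.
#' @param ... One or more integer counters (e.g. subject index, trial index).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  counters <- c(...)
  stopifnot(length(counters) >= 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (k in counters) {
    # affine mix per counter; doubles are exact well beyond these magnitudes
    h <- (h * 69069 + as.double(k) * 362437 + 1013904223) %% 2147483647
    h <- (h * 1103515245 + 12345) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spectral radius of the companion matrix of a VAR coefficient stack
#'
#' @param A List of p square coefficient matrices (lag 1..p). The process is
#'   stationary iff the returned value is < 1.
#' @return Largest eigenvalue modulus of the (M p) x (M p) companion matrix.
#' @export
companion_spectral_radius <- function(A) {
  stopifnot(is.list(A), length(A) >= 1L)
  M <- nrow(A[[1L]])
  p <- length(A)
  Cm <- matrix(0, M * p, M * p)
  for (d in seq_len(p)) Cm[seq_len(M), (d - 1L) * M + seq_len(M)] <- A[[d]]
  if (p > 1L) {
    Cm[M + seq_len(M * (p - 1L)), seq_len(M * (p - 1L))] <-
      diag(M * (p - 1L))
  }
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

num_fmt <- function(x) formatC(x, digits = 17, format = "g")
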