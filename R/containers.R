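#' Epoched multichannel data container
#'
#' Bundles a trials x channels x samples array with its sampling rate, channel
#' labels and positions, time axis and per-trial condition tags. This is the
#' exchange container between the generator, the spectral stage and the
#' sensor-level statistics.
#'
#' @param data Numeric array `[trials, channels, samples]`.
#' @param srate Sampling rate in Hz.
#' @param ch_names Character vector of channel labels (length = channels).
#' @param ch_pos Numeric matrix `[channels, 2]` or `[channels, 3]` of channel
#'   positions (arbitrary but consistent units; used for adjacency).
#' @param times Numeric vector of sample times in seconds relative to stimulus
#'   onset (length = samples). Defaults to `0, 1/srate, ...`.
#' @param condition Per-trial condition tag (length = trials), any atomic type.
#' @return An object of class `epoched_data`.
#' @export
epoched_data <- function(data, srate, ch_names = NULL, ch_pos = NULL,
                         times = NULL, condition = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!is.finite(srate) || srate <= 0) stop("srate must be a positive, finite number")
  nt <- dim(data)[1L]; nc <- dim(data)[2L]; ns <- dim(data)[3L]
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nc))
  if (is.null(times)) times <- seq(0, by = 1 / srate, length.out = ns)
  stopifnot(length(ch_names) == nc, length(times) == ns)
  if (!is.null(ch_pos)) {
    ch_pos <- as.matrix(ch_pos)
    stopifnot(nrow(ch_pos) == nc)
  }
  if (!is.null(condition)) stopifnot(length(condition) == nt)
  structure(list(data = data, srate = srate, ch_names = ch_names,
                 ch_pos = ch_pos, times = times, condition = condition),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_data> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$srate))
  cat(sprintf("  time %g .. %g s", min(x$times), max(x$times)))
  if (!is.null(x$condition))
    cat(sprintf(" | conditions: %s", paste(unique(x$condition), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Write / read epoched data to the pipeline container
#'
#' The container is a directory holding the sample array as full-precision
#' text plus a JSON metadata sidecar; the round trip is lossless for doubles
#' (17 significant digits).
#'
#' @param x An [epoched_data] object.
#' @param path Directory to create/overwrite.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   reconstructed [epoched_data].
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoched_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(num_fmt(as.vector(x$data)), file.path(path, "data.txt"))
  meta <- list(dim = dim(x$data), srate = x$srate, ch_names = x$ch_names,
               times = num_fmt(x$times), condition = x$condition,
               convention = "data.txt holds the [trials x channels x samples] array in R column-major order; times in seconds relative to stimulus onset")
  if (!is.null(x$ch_pos)) meta$ch_pos <- apply(x$ch_pos, 2L, num_fmt)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  vals <- as.numeric(readLines(file.path(path, "data.txt")))
  data <- array(vals, dim = as.integer(meta$dim))
  ch_pos <- if (!is.null(meta$ch_pos)) {
    m <- as.matrix(meta$ch_pos); storage.mode(m) <- "double"; m
  }
  epoched_data(data, srate = meta$srate, ch_names = meta$ch_names,
               ch_pos = ch_pos, times = as.numeric(meta$times),
               condition = meta$condition)
}
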