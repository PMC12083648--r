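# DeerTrace container and its plain-text dialect.

#' A single dipolar evolution trace
#'
#' @param t Time grid, microseconds; strictly increasing, first point in
#'   \code{[0, first spacing)}.
#' @param v Real, normalised signal; same length as \code{t} (>= 16 points).
#' @param condition Condition label (e.g. "apo", "MgATP-Sph").
#' @param pair Spin-label pair label (e.g. "T193-M298").
#' @param noise_sigma Optional known per-point noise scale; when absent the
#'   fit engine estimates it with [estimate_noise()].
#' @return A \code{deer_trace} object.
#' @export
deer_trace <- function(t, v, condition = "default", pair = "pair", noise_sigma = NULL) {
  if (length(t) != length(v)) stop("`t` and `v` must have equal length")
  if (length(t) < 16L) stop("a trace needs at least 16 points")
  if (any(!is.finite(t)) || any(diff(t) <= 0)) stop("`t` must be finite and strictly increasing")
  dt1 <- t[2] - t[1]
  if (t[1] < 0 || t[1] >= dt1) stop("first time point must lie in [0, first spacing)")
  if (any(!is.finite(v))) stop("all signal values must be finite")
  if (!is.null(noise_sigma)) {
    stopifnot(is.numeric(noise_sigma), length(noise_sigma) == 1L, noise_sigma >= 0)
    if (noise_sigma == 0) noise_sigma <- NULL
  }
  structure(list(t = as.numeric(t), v = as.numeric(v),
                 condition = as.character(condition), pair = as.character(pair),
                 noise_sigma = noise_sigma),
            class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  cat(sprintf("DEER trace '%s' / condition '%s': %d points, t in [%.3g, %.3g] us%s\n",
              x$pair, x$condition, length(x$t), x$t[1], x$t[length(x$t)],
              if (is.null(x$noise_sigma)) "" else sprintf(", noise sigma %.3g", x$noise_sigma)))
  invisible(x)
}

#' Read a DEER trace from its two-column text dialect
#'
#' Comment lines start with \code{#}; the optional header keys
#' \code{# condition:} and \code{# pair:} (and \code{# noise_sigma:}) are
#' honoured. Data lines hold two comma- or whitespace-separated columns:
#' time in microseconds and signal.
#'
#' @param path File path.
#' @return A [deer_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  condition <- "default"; pair <- "pair"; noise_sigma <- NULL
  tt <- numeric(0); vv <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      if (grepl("^condition\\s*:", body)) condition <- trimws(sub("^condition\\s*:", "", body))
      if (grepl("^pair\\s*:", body)) pair <- trimws(sub("^pair\\s*:", "", body))
      if (grepl("^noise_sigma\\s*:", body))
        noise_sigma <- as.numeric(trimws(sub("^noise_sigma\\s*:", "", body)))
      next
    }
    parts <- strsplit(ln, "[,\\s]+", perl = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2L || any(is.na(vals[1:2])))
      stop(sprintf("malformed trace line %d in %s: '%s'", i, path, lines[i]))
    tt <- c(tt, vals[1]); vv <- c(vv, vals[2])
  }
  if (any(diff(tt) <= 0)) stop(sprintf("non-increasing time axis in %s", path))
  deer_trace(tt, vv, condition = condition, pair = pair, noise_sigma = noise_sigma)
}

#' Write a DEER trace in the two-column text dialect
#'
#' @param trace A [deer_trace()].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "deer_trace"))
  hdr <- c(sprintf("# condition: %s", trace$condition),
           sprintf("# pair: %s", trace$pair))
  if (!is.null(trace$noise_sigma))
    hdr <- c(hdr, sprintf("# noise_sigma: %.17g", trace$noise_sigma))
  hdr <- c(hdr, "# t_us v")
  dat <- sprintf("%.17g %.17g", trace$t, trace$v)
  writeLines(c(hdr, dat), path)
  invisible(path)
}

#' Read every trace file in a directory
#'
#' @param dir Directory containing \code{.dat} / \code{.txt} trace files.
#' @return List of [deer_trace()] objects, sorted by file name.
#' @export
read_trace_dir <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("trace directory not found: %s", dir))
  files <- sort(list.files(dir, pattern = "\\.(dat|txt)$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no trace files (*.dat, *.txt) in %s", dir))
  lapply(files, read_trace)
}

#' Robust per-trace noise estimate
#'
#' Estimates the white-noise scale from the last 20\% of the decay. Each
#' point of the tail window is detrended against the local polynomial
#' through its neighbours (a third difference, which annihilates any
#' locally quadratic trend including the slowly varying background and
#' damped dipolar oscillation), and the robust MAD scale of the detrended
#' values is divided by \code{sqrt(20)}, the standard-deviation inflation
#' of a third difference of white noise.
#'
#' @param trace A [deer_trace()] with at least 32 points.
#' @return Estimated noise standard deviation (unitless signal units).
#' @export
estimate_noise <- function(trace) {
  stopifnot(inherits(trace, "deer_trace"))
  n <- length(trace$v)
  if (n < 32L) stop("noise estimation needs at least 32 points")
  m <- max(8L, ceiling(0.2 * n))
  tail_v <- trace$v[(n - m + 1L):n]
  d3 <- diff(tail_v, differences = 3L)
  mad(d3) / sqrt(20)
}
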