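# Forward physics: dipolar frequency, powder-averaged kernel, Gaussian
# mixture P(r), and the full signal model V(t) = V0 B(t) [1 - D(1 - F(t))].

#' Dipolar coupling frequency of a spin pair
#'
#' Frequency of the electron-electron dipolar interaction at inter-spin
#' distance \code{r}, using the nitroxide DEER convention
#' \eqn{\nu(r) = 52.04 \mathrm{MHz} \cdot (r/\mathrm{nm})^{-3}}.
#'
#' @param r Inter-spin distance in Angstrom; must be positive.
#' @return Frequency in MHz, same length as \code{r}.
#' @examples
#' dipolar_frequency(20)  # 52.04 / 8
#' @export
dipolar_frequency <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("`r` must be positive and finite (Angstrom)")
  52.04 / (r / 10)^3
}

#' Powder-averaged four-pulse DEER kernel
#'
#' Value of the orientation-averaged dipolar kernel
#' \eqn{K(t, r) = \int_0^1 \cos[(1 - 3u^2)\, 2\pi \nu(r)\, t]\, du},
#' evaluated through its Fresnel-integral closed form. \code{K(0, r) = 1}
#' and \code{|K| <= 1} everywhere.
#'
#' @param t Evolution time in microseconds, \code{t >= 0}.
#' @param r Distance in Angstrom, within the DEER-sensitive window
#'   \code{[10, 120]}.
#' @return Unitless kernel values (elementwise over recycled \code{t, r}).
#' @seealso [kernel_matrix()]
#' @export
kernel_value <- function(t, r) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0 (microseconds)")
  if (any(!is.finite(r)) || any(r < 10) || any(r > 120))
    stop("`r` must lie in [10, 120] Angstrom")
  theta <- 2 * pi * dipolar_frequency(r) * t   # dimensionless phase
  out <- rep(1, length(theta))
  big <- theta >= 1e-8
  if (any(big)) {
    th <- theta[big]
    z <- sqrt(6 * th / pi)
    out[big] <- sqrt(pi / (6 * th)) *
      (cos(th) * pracma::fresnelC(z) + sin(th) * pracma::fresnelS(z))
  }
  out
}

#' Kernel matrix on a time x distance grid
#'
#' @param t Time grid, microseconds.
#' @param r Distance grid, Angstrom.
#' @return Matrix with element \code{[i, j] = kernel_value(t[i], r[j])}.
#' @export
kernel_matrix <- function(t, r) {
  if (length(t) == 0L || length(r) == 0L) stop("empty time or distance grid")
  outer(t, r, kernel_value)
}

#' Default distance grid for P(r)
#'
#' Uniform 0.2 Angstrom grid over the DEER-sensitive range 15-90 Angstrom.
#'
#' @param from,to,by Grid limits and spacing, Angstrom.
#' @return Numeric vector of distances.
#' @export
default_r_grid <- function(from = 15, to = 90, by = 0.2) seq(from, to, by = by)

# trapezoid quadrature weights for an arbitrary (sorted) grid
trapz_weights <- function(r) {
  n <- length(r)
  if (n < 2L) stop("grid needs at least 2 points")
  d <- diff(r)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' Single Gaussian distance component
#'
#' @param r0 Center distance, Angstrom, in \code{[15, 90]}.
#' @param sigma Standard deviation, Angstrom, in \code{[0.5, 15]}.
#' @return A \code{gauss_component} object.
#' @export
gauss_component <- function(r0, sigma) {
  if (!is.numeric(r0) || length(r0) != 1L || r0 < 15 || r0 > 90)
    stop("`r0` must be a single value in [15, 90] Angstrom")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0.5 || sigma > 15)
    stop("`sigma` must be a single value in [0.5, 15] Angstrom")
  structure(list(r0 = r0, sigma = sigma), class = "gauss_component")
}

#' Gaussian mixture specification shared across conditions
#'
#' A set of Gaussian components (centers and widths shared by every
#' condition) together with one amplitude vector per condition on the
#' probability simplex. Components are canonically ordered by ascending
#' center (ties by ascending width); amplitude columns are permuted to
#' match.
#'
#' @param r0 Numeric vector of component centers, Angstrom.
#' @param sigma Numeric vector of component widths, Angstrom (same length).
#' @param amplitudes Matrix (or coercible) with one row per condition and
#'   one column per component; rows must be nonnegative and sum to 1 within
#'   1e-9. Row names are the condition labels.
#' @return A \code{mixture_spec} object.
#' @examples
#' mixture_spec(c(40, 55), c(3, 4),
#'              rbind(apo = c(0.3, 0.7), bound = c(0.8, 0.2)))
#' @export
mixture_spec <- function(r0, sigma, amplitudes) {
  if (length(r0) != length(sigma) || length(r0) < 1L)
    stop("`r0` and `sigma` must have equal positive length")
  for (i in seq_along(r0)) gauss_component(r0[i], sigma[i])  # bounds check
  a <- as.matrix(amplitudes)
  if (is.null(rownames(a))) rownames(a) <- paste0("condition", seq_len(nrow(a)))
  if (ncol(a) != length(r0)) stop("amplitude matrix needs one column per component")
  if (any(a < 0)) stop("amplitudes must be nonnegative")
  if (any(abs(rowSums(a) - 1) > 1e-9)) stop("each amplitude row must sum to 1 within 1e-9")
  ord <- order(r0, sigma)
  structure(list(r0 = r0[ord], sigma = sigma[ord], amplitudes = a[, ord, drop = FALSE]),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("Gaussian mixture: %d component(s), %d condition(s)\n",
              length(x$r0), nrow(x$amplitudes)))
  cat("  centers (A):", paste(sprintf("%.2f", x$r0), collapse = ", "), "\n")
  cat("  widths  (A):", paste(sprintf("%.2f", x$sigma), collapse = ", "), "\n")
  amp <- round(x$amplitudes, 4)
  colnames(amp) <- sprintf("a%d", seq_len(ncol(amp)))
  print(amp)
  invisible(x)
}

#' Per-trace nuisance parameters of the DEER signal
#'
#' @param depth Modulation depth in (0, 1).
#' @param bg_rate Intermolecular background decay rate, 1/microsecond, >= 0.
#' @param bg_dim Background dimensionality in (2, 3.5]; 3 gives a pure
#'   exponential (homogeneous 3D spin bath).
#' @param scale Overall amplitude V0 > 0.
#' @return A \code{trace_nuisance} object.
#' @export
trace_nuisance <- function(depth, bg_rate, bg_dim = 3, scale = 1) {
  if (depth <= 0 || depth >= 1) stop("`depth` must be in (0, 1)")
  if (bg_rate < 0) stop("`bg_rate` must be >= 0")
  if (bg_dim <= 2 || bg_dim > 3.5) stop("`bg_dim` must be in (2, 3.5]")
  if (scale <= 0) stop("`scale` must be > 0")
  structure(list(depth = depth, bg_rate = bg_rate, bg_dim = bg_dim, scale = scale),
            class = "trace_nuisance")
}

# component density columns, each trapezoid-normalised to integrate to 1
component_densities <- function(r, r0, sigma, w = trapz_weights(r)) {
  G <- vapply(seq_along(r0), function(i) dnorm(r, r0[i], sigma[i]), numeric(length(r)))
  G <- matrix(G, nrow = length(r))
  norms <- colSums(w * G)
  if (any(norms <= 0)) stop("component density vanishes on the grid")
  sweep(G, 2, norms, "/")
}

#' Evaluate a mixture's distance distribution for one condition
#'
#' Each component Gaussian is normalised on the grid by trapezoid
#' quadrature, then combined with the condition's simplex amplitudes, so the
#' trapezoidal integral of the result is exactly 1.
#'
#' @param spec A [mixture_spec()].
#' @param condition Condition label (a row name of \code{spec$amplitudes}).
#' @param r Distance grid, Angstrom; must span \code{r0 +/- 5 sigma} for
#'   every component.
#' @return A \code{distance_distribution}: list with \code{r} and density
#'   \code{p} (1/Angstrom).
#' @export
evaluate_mixture <- function(spec, condition, r = default_r_grid()) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!condition %in% rownames(spec$amplitudes))
    stop(sprintf("condition '%s' not present in mixture spec", condition))
  if (min(r) > min(spec$r0 - 5 * spec$sigma) || max(r) < max(spec$r0 + 5 * spec$sigma))
    stop("distance grid must span r0 +/- 5 sigma for every component")
  G <- component_densities(r, spec$r0, spec$sigma)
  p <- as.vector(G %*% spec$amplitudes[condition, ])
  structure(list(r = r, p = p), class = "distance_distribution")
}

#' Full DEER signal model for one trace
#'
#' \eqn{V(t) = V_0 \, B(t)\, [1 - \Delta(1 - F(t))]} with stretched
#' background \eqn{B(t) = \exp(-k t^{d/3})} and form factor
#' \eqn{F(t) = \sum_i a_i \int G_i(r) K(t, r)\, dr} evaluated on a discrete
#' distance grid via the kernel matrix.
#'
#' @inheritParams evaluate_mixture
#' @param nuisance A [trace_nuisance()].
#' @param t Time grid, microseconds.
#' @param r Distance grid used to discretise P(r).
#' @return Numeric signal vector, unitless; equals \code{scale} at t = 0.
#' @export
model_signal <- function(spec, nuisance, condition, t, r = default_r_grid()) {
  stopifnot(inherits(nuisance, "trace_nuisance"))
  pd <- evaluate_mixture(spec, condition, r)
  K <- kernel_matrix_cached(t, r)
  w <- trapz_weights(r)
  FF <- as.vector(K %*% (w * pd$p))
  B <- exp(-nuisance$bg_rate * t^(nuisance$bg_dim / 3))
  nuisance$scale * B * (1 - nuisance$depth * (1 - FF))
}
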