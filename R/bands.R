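# Delta-method confidence bands on P(r).

#' Confidence band on a fitted distance distribution
#'
#' Propagates the free-parameter covariance onto the density by the delta
#' method: at every grid point the band is
#' \eqn{p(r) \pm n_\sigma \sqrt{g^\top C g}}, with \eqn{g} the gradient of
#' the density with respect to the free parameters at the optimum and
#' \eqn{C} the Jacobian-based covariance scaled by the reduced chi-square.
#' The lower envelope is clipped at zero.
#'
#' @param fit A converged \code{deer_global_fit}.
#' @param condition Condition label.
#' @param r Distance grid (defaults to the fit grid).
#' @param n_sigma Band half-width in standard deviations (2 by default).
#' @return List with \code{r}, best-fit density \code{p}, and \code{lower},
#'   \code{upper} envelopes (1/Angstrom).
#' @export
confidence_band <- function(fit, condition, r = fit$r_grid, n_sigma = 2) {
  stopifnot(inherits(fit, "deer_global_fit"), isTRUE(fit$converged))
  x0 <- fit$x_opt
  p0 <- fit_density(fit, condition, r, x0)
  pm <- fit$pmap
  cc <- match(condition, fit$conditions)
  sc <- if (pm$share_widths) 1L else cc
  active <- c(pm$i_r0, pm$i_sig[, sc],
              if (pm$k > 1L) pm$i_amp[[cc]] else integer(0))
  G <- matrix(0, length(r), pm$npar)
  h <- 1e-5
  for (ip in active) {
    xp <- x0; xp[ip] <- xp[ip] + h
    xm <- x0; xm[ip] <- xm[ip] - h
    G[, ip] <- (fit_density(fit, condition, r, xp) -
                fit_density(fit, condition, r, xm)) / (2 * h)
  }
  v <- rowSums((G %*% fit$covariance) * G)
  v[v < 0] <- 0
  half <- n_sigma * sqrt(v)
  list(r = r, p = p0, lower = pmax(0, p0 - half), upper = p0 + half,
       n_sigma = n_sigma)
}
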