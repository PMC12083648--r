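# S3 methods for deer_global_fit.

# natural values, names, and d(natural)/d(internal) for every free parameter
natural_param_table <- function(fit) {
  pm <- fit$pmap; opts <- fit$options
  th <- unpack_pars(fit$x_opt, pm, opts)
  val <- numeric(pm$npar); dnat <- numeric(pm$npar)
  val[pm$i_r0] <- th$r0;            dnat[pm$i_r0] <- th$dr0dx
  val[pm$i_sig] <- th$sigma;        dnat[pm$i_sig] <- th$dsigdx
  if (pm$k > 1L) for (cc in seq_len(pm$C)) {
    # report the logit itself; amplitude uncertainties come from the softmax delta
    val[pm$i_amp[[cc]]] <- fit$x_opt[pm$i_amp[[cc]]]
    dnat[pm$i_amp[[cc]]] <- 1
  }
  iu <- unique(pm$i_depth)
  val[iu] <- th$depth[match(iu, pm$i_depth)]
  dnat[iu] <- th$ddepthdx[match(iu, pm$i_depth)]
  val[pm$i_bg] <- th$bg;            dnat[pm$i_bg] <- th$bg
  val[pm$i_scale] <- th$scale;      dnat[pm$i_scale] <- th$scale
  se <- sqrt(pmax(diag(fit$covariance), 0)) * abs(dnat)
  data.frame(name = pm$par_names, value = val, se = se, dnat = dnat,
             stringsAsFactors = FALSE)
}

# amplitude standard errors per condition via the softmax delta method
amplitude_se <- function(fit) {
  pm <- fit$pmap
  out <- matrix(0, pm$C, pm$k, dimnames = dimnames(fit$amplitudes))
  if (pm$k == 1L) return(out)
  for (cc in seq_len(pm$C)) {
    a <- fit$amplitudes[cc, ]
    ia <- pm$i_amp[[cc]]
    Ca <- fit$covariance[ia, ia, drop = FALSE]
    Da <- matrix(0, pm$k, pm$k - 1L)       # da_m / dz_l
    for (l in seq_len(pm$k - 1L)) {
      da <- -a * a[l + 1L]; da[l + 1L] <- da[l + 1L] + a[l + 1L]
      Da[, l] <- da
    }
    out[cc, ] <- sqrt(pmax(diag(Da %*% Ca %*% t(Da)), 0))
  }
  out
}

#' @export
print.deer_global_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("Global DEER fit (k = %s) FAILED to converge\n", x$k))
    if (!is.null(x$messages)) cat("  ", paste(x$messages, collapse = "\n   "), "\n")
    return(invisible(x))
  }
  cat(sprintf("Global DEER fit, pair '%s': %d component(s), %d condition(s), %d trace(s)\n",
              x$pair, x$k, length(x$conditions), length(x$traces)))
  tab <- natural_param_table(x)
  r0 <- tab[grepl("^r0_", tab$name), ]
  sg <- tab[grepl("^sigma_", tab$name), ]
  for (i in seq_len(x$k))
    cat(sprintf("  component %d: r0 = %.2f +/- %.2f A, sigma = %.2f +/- %.2f A\n",
                i, r0$value[i], r0$se[i], sg$value[i], sg$se[i]))
  cat("Per-condition amplitudes:\n")
  amp <- x$amplitudes; ase <- amplitude_se(x)
  for (cc in seq_len(nrow(amp)))
    cat(sprintf("  %-12s %s\n", rownames(amp)[cc],
                paste(sprintf("%.3f+/-%.3f", amp[cc, ], ase[cc, ]), collapse = "  ")))
  cat(sprintf("chi2_red = %.4g on %d points, %d free parameters; AICc = %.2f, BIC = %.2f\n",
              x$chi2_red, x$n_obs, x$n_params, x$criteria[["AICc"]], x$criteria[["BIC"]]))
  invisible(x)
}

#' @export
summary.deer_global_fit <- function(object, ...) {
  stopifnot(isTRUE(object$converged))
  tab <- natural_param_table(object)
  nuis <- data.frame(
    trace = seq_along(object$traces),
    condition = vapply(object$traces, `[[`, character(1), "condition"),
    depth = vapply(object$nuisances, `[[`, numeric(1), "depth"),
    bg_rate = vapply(object$nuisances, `[[`, numeric(1), "bg_rate"),
    scale = vapply(object$nuisances, `[[`, numeric(1), "scale"),
    noise_sigma = object$noise_sigmas)
  structure(list(fit = object, params = tab[, c("name", "value", "se")],
                 nuisances = nuis, amplitudes = object$amplitudes,
                 amplitude_se = amplitude_se(object)),
            class = "summary.deer_global_fit")
}

#' @export
print.summary.deer_global_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-trace nuisance parameters:\n")
  print(transform(x$nuisances, depth = round(depth, 4), bg_rate = signif(bg_rate, 4),
                  scale = signif(scale, 5), noise_sigma = signif(noise_sigma, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.deer_global_fit <- function(object, ...) {
  stopifnot(isTRUE(object$converged))
  out <- c(setNames(object$r0, sprintf("r0_%d", seq_len(object$k))))
  if (!is.null(object$spec))
    out <- c(out, setNames(object$spec$sigma, sprintf("sigma_%d", seq_len(object$k))))
  amp <- object$amplitudes
  for (cc in seq_len(nrow(amp)))
    out <- c(out, setNames(amp[cc, ], sprintf("ampl_%d.%s", seq_len(ncol(amp)),
                                              rownames(amp)[cc])))
  for (j in seq_along(object$nuisances)) {
    nu <- object$nuisances[[j]]
    out <- c(out, setNames(c(nu$depth, nu$bg_rate, nu$scale),
                           sprintf(c("depth.%d", "bg_rate.%d", "scale.%d"), j)))
  }
  out
}

#' @export
vcov.deer_global_fit <- function(object, ...) {
  stopifnot(isTRUE(object$converged))
  tab <- natural_param_table(object)
  D <- diag(tab$dnat, nrow = length(tab$dnat))
  V <- D %*% object$covariance %*% D
  dimnames(V) <- list(tab$name, tab$name)
  V
}

#' @export
residuals.deer_global_fit <- function(object, type = c("raw", "weighted"), ...) {
  stopifnot(isTRUE(object$converged))
  type <- match.arg(type)
  out <- object$residuals
  if (type == "weighted")
    out <- lapply(seq_along(out), function(j) out[[j]] / object$noise_sigmas[j])
  names(out) <- vapply(object$traces, `[[`, character(1), "condition")
  out
}

#' @export
fitted.deer_global_fit <- function(object, ...) {
  stopifnot(isTRUE(object$converged))
  out <- object$fitted_signals
  names(out) <- vapply(object$traces, `[[`, character(1), "condition")
  out
}

#' Predict signals or distance distributions from a fitted model
#'
#' @param object A converged \code{deer_global_fit}.
#' @param type \code{"signal"} (a model trace) or \code{"distribution"}
#'   (the condition's P(r)).
#' @param condition Condition label; defaults to the first.
#' @param t Time grid for \code{type = "signal"}; defaults to the grid of
#'   the first trace of that condition.
#' @param trace Trace index whose nuisance parameters are used for
#'   \code{type = "signal"}; defaults to the condition's first trace.
#' @param r Distance grid for \code{type = "distribution"}.
#' @param ... Unused.
#' @return Numeric signal vector, or a \code{distance_distribution}.
#' @export
predict.deer_global_fit <- function(object, type = c("signal", "distribution"),
                                    condition = NULL, t = NULL, trace = NULL,
                                    r = object$r_grid, ...) {
  stopifnot(isTRUE(object$converged))
  type <- match.arg(type)
  if (is.null(condition)) condition <- object$conditions[1]
  cc <- match(condition, object$conditions)
  if (is.na(cc)) stop(sprintf("unknown condition '%s'", condition))
  if (type == "distribution") return(distance_distribution(object, condition, r))
  if (is.null(trace)) trace <- which(object$trace_cond == cc)[1]
  if (is.null(t)) t <- object$traces[[trace]]$t
  nu <- object$nuisances[[trace]]
  p <- fit_density(object, condition, r)
  K <- kernel_matrix_cached(t, r)
  FF <- as.vector(K %*% (trapz_weights(r) * p))
  nu$scale * exp(-nu$bg_rate * t^(nu$bg_dim / 3)) * (1 - nu$depth * (1 - FF))
}

#' Simulate noisy traces from a fitted model
#'
#' @param object A converged \code{deer_global_fit}.
#' @param nsim Number of replicate trace sets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of \code{nsim} lists of [deer_trace()] objects mirroring
#'   the fitted traces, with Gaussian noise at each trace's noise scale.
#' @export
simulate.deer_global_fit <- function(object, nsim = 1, seed = 1L, ...) {
  stopifnot(isTRUE(object$converged))
  lapply(seq_len(nsim), function(s) {
    lapply(seq_along(object$traces), function(j) {
      tr <- object$traces[[j]]
      mu <- predict(object, "signal", condition = tr$condition,
                    t = tr$t, trace = j)
      set.seed((seed + 7919L * (s - 1L) + j) %% .Machine$integer.max)
      deer_trace(tr$t, mu + rnorm(length(mu), 0, object$noise_sigmas[j]),
                 condition = tr$condition, pair = tr$pair,
                 noise_sigma = object$noise_sigmas[j])
    })
  })
}

#' Plot a global DEER fit
#'
#' \code{which = "traces"} overlays the data and fitted decays (offset per
#' trace); \code{which = "distributions"} draws each condition's P(r) with
#' its 2-sigma confidence band.
#'
#' @param x A converged \code{deer_global_fit}.
#' @param which \code{"traces"} or \code{"distributions"}.
#' @param n_sigma Band half-width for the distribution panel.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.deer_global_fit <- function(x, which = c("distributions", "traces"),
                                 n_sigma = 2, ...) {
  stopifnot(isTRUE(x$converged))
  which <- match.arg(which)
  if (which == "traces") {
    off <- 0
    plot(NA, xlim = range(unlist(lapply(x$traces, `[[`, "t"))),
         ylim = c(0, length(x$traces) * 0.45 + 1.1),
         xlab = "t (us)", ylab = "V(t) + offset", main = x$pair, ...)
    for (j in seq_along(x$traces)) {
      tr <- x$traces[[j]]
      points(tr$t, tr$v / x$nuisances[[j]]$scale + off, pch = 16, cex = 0.3,
             col = "grey40")
      lines(tr$t, x$fitted_signals[[j]] / x$nuisances[[j]]$scale + off,
            col = "firebrick", lwd = 1.5)
      off <- off + 0.45
    }
  } else {
    cols <- seq_along(x$conditions) + 1
    bands <- lapply(x$conditions, function(cd) confidence_band(x, cd, n_sigma = n_sigma))
    ymax <- max(vapply(bands, function(b) max(b$upper), numeric(1)))
    plot(NA, xlim = range(x$r_grid), ylim = c(0, 1.05 * ymax),
         xlab = "r (A)", ylab = "P(r) (1/A)", main = x$pair, ...)
    for (i in seq_along(bands)) {
      b <- bands[[i]]
      polygon(c(b$r, rev(b$r)), c(b$lower, rev(b$upper)),
              col = adjustcolor(cols[i], 0.25), border = NA)
      lines(b$r, b$p, col = cols[i], lwd = 2)
    }
    legend("topright", legend = x$conditions, col = cols, lwd = 2, bty = "n")
  }
  invisible(x)
}
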