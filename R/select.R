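# Choice of the number of Gaussian components by an information criterion.

#' Select the number of Gaussian components
#'
#' Fits the global model for every k from 1 to \code{options$k_max} and
#' returns the k minimising the chosen criterion (AICc by default; BIC is
#' reported alongside). With the noise-scaled residuals the criteria take
#' the known-variance Gaussian form \eqn{\chi^2 + \mathrm{penalty}}. Ties
#' break toward the smaller k.
#'
#' @inheritParams deer_global_fit
#' @return A \code{deer_model_scan}: list with \code{best_k},
#'   \code{best_fit}, all \code{fits}, and a criteria \code{table}.
#' @export
select_components <- function(traces, options = fit_options()) {
  stopifnot(inherits(options, "fit_options"))
  ks <- seq_len(options$k_max)
  fits <- lapply(ks, function(k) deer_global_fit(traces, k, options))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no candidate component count converged")
  crit <- vapply(fits, function(f)
    if (isTRUE(f$converged)) unname(f$criteria[options$criterion]) else Inf,
    numeric(1))
  best_k <- ks[which.min(crit)]        # which.min takes the first (smallest k) on ties
  tab <- data.frame(
    k = ks,
    AICc = vapply(fits, function(f) if (isTRUE(f$converged)) f$criteria[["AICc"]] else NA_real_, numeric(1)),
    BIC = vapply(fits, function(f) if (isTRUE(f$converged)) f$criteria[["BIC"]] else NA_real_, numeric(1)),
    chi2_red = vapply(fits, function(f) if (isTRUE(f$converged)) f$chi2_red else NA_real_, numeric(1)),
    n_params = vapply(fits, function(f) if (isTRUE(f$converged)) f$n_params else NA_integer_, integer(1)),
    converged = ok)
  structure(list(best_k = best_k, best_fit = fits[[best_k]], fits = fits,
                 table = tab, criterion = options$criterion),
            class = "deer_model_scan")
}

#' @export
print.deer_model_scan <- function(x, ...) {
  cat(sprintf("Component scan (criterion: %s), best k = %d\n", x$criterion, x$best_k))
  print(transform(x$table, AICc = round(AICc, 2), BIC = round(BIC, 2),
                  chi2_red = round(chi2_red, 4)), row.names = FALSE)
  invisible(x)
}

#' Agreement between individual and global analysis
#'
#' The consistency check of fitting each condition's traces on their own at
#' the same component count as the global fit, then measuring the
#' total-variation distance (half the L1 distance on the grid) between each
#' condition's individual and global P(r).
#'
#' @inheritParams deer_global_fit
#' @param k Component count; if \code{NULL} it is chosen by
#'   [select_components()] on the pooled traces.
#' @return Data frame with columns \code{condition} and \code{tv} (the
#'   total-variation distance, in \code{[0, 1]}); the global and individual
#'   fits are attached as attributes.
#' @export
compare_individual_global <- function(traces, options = fit_options(), k = NULL) {
  if (is.null(k)) k <- select_components(traces, options)$best_k
  global <- deer_global_fit(traces, k, options)
  if (!isTRUE(global$converged)) stop("global fit did not converge")
  rg <- global$r_grid; w <- trapz_weights(rg)
  conds <- global$conditions
  indiv <- vector("list", length(conds)); names(indiv) <- conds
  tv <- numeric(length(conds))
  for (i in seq_along(conds)) {
    sub <- traces[vapply(traces, function(tr) tr$condition == conds[i], logical(1))]
    fi <- deer_global_fit(sub, k, options)
    if (!isTRUE(fi$converged)) stop(sprintf("individual fit failed for condition '%s'", conds[i]))
    indiv[[i]] <- fi
    pg <- fit_density(global, conds[i], rg)
    pi_ <- fit_density(fi, conds[i], rg)
    tv[i] <- 0.5 * sum(w * abs(pg - pi_))
  }
  out <- data.frame(condition = conds, tv = tv)
  attr(out, "global") <- global
  attr(out, "individual") <- indiv
  out
}
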