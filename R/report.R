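# Structured output: JSON fit report plus per-condition P(r) CSVs.

#' Write a fit report and per-condition distribution CSVs
#'
#' Emits \code{report.json} (parameters with uncertainties, information
#' criteria, fit diagnostics) and one \code{pr_<condition>.csv} per
#' condition with columns \code{r_A, p, lower, upper} (the best-fit density
#' and its confidence band).
#'
#' @param fit A converged \code{deer_global_fit}.
#' @param dir Output directory (created if needed).
#' @param n_sigma Band half-width in standard deviations.
#' @param scan Optional \code{deer_model_scan} whose criteria table is
#'   embedded in the report.
#' @param seed Optional seed to record in the report.
#' @return Invisibly, the report path.
#' @export
write_fit_report <- function(fit, dir, n_sigma = 2, scan = NULL, seed = NULL) {
  stopifnot(inherits(fit, "deer_global_fit"), isTRUE(fit$converged))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- natural_param_table(fit)
  ase <- amplitude_se(fit)
  rpt <- list(
    package = "deerstate",
    version = as.character(packageVersion("deerstate")),
    pair = fit$pair,
    k = fit$k,
    conditions = fit$conditions,
    chi2_red = fit$chi2_red,
    n_obs = fit$n_obs,
    n_params = fit$n_params,
    criteria = as.list(fit$criteria),
    components = lapply(seq_len(fit$k), function(i) list(
      r0_A = tab$value[tab$name == sprintf("r0_%d", i)],
      r0_se_A = tab$se[tab$name == sprintf("r0_%d", i)],
      sigma_A = if (!is.null(fit$spec)) fit$spec$sigma[i] else NULL)),
    amplitudes = lapply(fit$conditions, function(cd) list(
      condition = cd,
      a = as.numeric(fit$amplitudes[cd, ]),
      se = as.numeric(ase[cd, ]))),
    noise_sigma = as.numeric(fit$noise_sigmas))
  if (!is.null(seed)) rpt$seed <- seed
  if (!is.null(scan)) {
    rpt$selection <- list(best_k = scan$best_k, criterion = scan$criterion,
                          table = scan$table)
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(rpt, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  for (cd in fit$conditions) {
    b <- confidence_band(fit, cd, n_sigma = n_sigma)
    write.csv(data.frame(r_A = b$r, p = b$p, lower = b$lower, upper = b$upper),
              file.path(dir, sprintf("pr_%s.csv", gsub("[^A-Za-z0-9_-]", "_", cd))),
              row.names = FALSE)
  }
  invisible(path)
}
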