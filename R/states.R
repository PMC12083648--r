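# Mapping fitted Gaussian components to named reference structural states
# and tabulating per-condition state populations.

#' Read a reference-state table
#'
#' CSV with columns \code{name, pair, r0_A, sigma_A, source}; each row is a
#' named structural state (e.g. "apo-open", "closed") with the Gaussian
#' summary of its predicted spin-pair distance distribution (typically
#' exported from rotamer-library software run on a crystal structure or
#' model).
#'
#' @param path CSV file path.
#' @return Data frame with columns \code{name, pair, r0, sigma, source}.
#' @export
read_reference_states <- function(path) {
  if (!file.exists(path)) stop(sprintf("reference-state file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "pair", "r0_A", "sigma_A")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("reference CSV missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (is.null(df$source)) df$source <- ""
  out <- data.frame(name = as.character(df$name), pair = as.character(df$pair),
                    r0 = as.numeric(df$r0_A), sigma = as.numeric(df$sigma_A),
                    source = as.character(df$source), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) gauss_component(out$r0[i], out$sigma[i])
  out
}

#' Write a reference-state table
#' @param refs Data frame as returned by [read_reference_states()].
#' @param path Output CSV path.
#' @export
write_reference_states <- function(refs, path) {
  write.csv(data.frame(name = refs$name, pair = refs$pair, r0_A = refs$r0,
                       sigma_A = refs$sigma, source = refs$source),
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# overlap coefficient of two grid-normalised densities
overlap_coefficient <- function(p1, p2, w) sum(w * pmin(p1, p2))

#' Assign fitted components to reference states by overlap
#'
#' For every fitted component, the overlap coefficient
#' \eqn{\mathrm{OVL} = \int \min(G_{comp}, G_{ref})\, dr} with each
#' reference state's Gaussian is computed on the fit grid (both densities
#' grid-normalised, so identical Gaussians give OVL = 1). The component maps
#' to the reference with the largest OVL when that OVL reaches
#' \code{min_overlap}, otherwise to \code{"unassigned"}. Several components
#' may map to the same state.
#'
#' @param fit A converged \code{deer_global_fit}.
#' @param refs Reference-state data frame ([read_reference_states()]); its
#'   \code{pair} must match the fit's pair label.
#' @param min_overlap Assignment threshold in \code{[0, 1]}.
#' @return Data frame with one row per component: \code{component, r0,
#'   sigma, state, ovl}.
#' @export
assign_components <- function(fit, refs, min_overlap = 0.25) {
  stopifnot(inherits(fit, "deer_global_fit"), isTRUE(fit$converged))
  if (nrow(refs) == 0L) stop("reference-state table is empty")
  if (!all(refs$pair == fit$pair))
    stop(sprintf("reference pair label(s) %s do not match fit pair '%s'",
                 paste(unique(refs$pair), collapse = ", "), fit$pair))
  rg <- fit$r_grid; w <- trapz_weights(rg)
  sig <- if (!is.null(fit$spec)) fit$spec$sigma else rowMeans(fit$sigma_by_condition)
  comp_d <- component_densities(rg, fit$r0, sig, w)
  ref_d <- component_densities(rg, refs$r0, refs$sigma, w)
  out <- data.frame(component = seq_len(fit$k), r0 = fit$r0, sigma = sig,
                    state = "unassigned", ovl = 0, stringsAsFactors = FALSE)
  for (i in seq_len(fit$k)) {
    ov <- vapply(seq_len(nrow(refs)), function(j)
      overlap_coefficient(comp_d[, i], ref_d[, j], w), numeric(1))
    jbest <- which.max(ov)
    out$ovl[i] <- ov[jbest]
    if (ov[jbest] >= min_overlap) out$state[i] <- refs$name[jbest]
  }
  out
}

#' Per-condition state population table
#'
#' Sums each condition's component amplitudes by assigned state. Rows are
#' conditions, columns the reference-state names plus \code{"unassigned"};
#' every row sums to 1.
#'
#' @param fit A converged \code{deer_global_fit}.
#' @param mapping Assignment data frame from [assign_components()].
#' @return Matrix of population fractions (conditions x states).
#' @export
population_table <- function(fit, mapping) {
  stopifnot(inherits(fit, "deer_global_fit"), isTRUE(fit$converged))
  if (nrow(mapping) != fit$k) stop("mapping must cover every fitted component")
  states <- unique(c(setdiff(mapping$state, "unassigned"), "unassigned"))
  amp <- fit$amplitudes
  tab <- matrix(0, nrow(amp), length(states),
                dimnames = list(rownames(amp), states))
  for (i in seq_len(fit$k))
    tab[, mapping$state[i]] <- tab[, mapping$state[i]] + amp[, i]
  tab
}

#' Population shift between two conditions
#'
#' @param table Population matrix from [population_table()].
#' @param condition_a,condition_b Row labels; the shift is
#'   \code{condition_b - condition_a} per state, so positive values mark
#'   states preferentially populated under condition b. The deltas sum to 0.
#' @return Named numeric vector of per-state deltas.
#' @export
population_shift <- function(table, condition_a, condition_b) {
  for (cond in c(condition_a, condition_b))
    if (!cond %in% rownames(table)) stop(sprintf("unknown condition '%s'", cond))
  table[condition_b, ] - table[condition_a, ]
}
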