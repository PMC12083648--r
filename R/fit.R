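# Global Levenberg-Marquardt fitting of the Gaussian-mixture DEER model.
#
# Free parameters live on unconstrained scales: centers and widths through a
# logistic box transform, per-condition amplitudes through a softmax with the
# first component as baseline (so the simplex constraint is exact), depth
# through a logit, background rate and amplitude scale through logs.

#' Options controlling the global DEER fit
#'
#' @param k_max Maximum number of Gaussian components scanned by
#'   [select_components()].
#' @param criterion Model-selection rule, \code{"AICc"} (small-sample
#'   corrected, default) or \code{"BIC"}; both are always reported.
#' @param n_restarts Multistart count; centers are initialised from a seeded
#'   scrambled Halton sequence over \code{[25, 65]} Angstrom.
#' @param seed Integer seed making the whole fit deterministic.
#' @param share_widths If \code{TRUE} (default) component widths are shared
#'   across conditions, i.e. a shared component means shared (r0, sigma).
#' @param share_depth If \code{TRUE} a single modulation depth is shared by
#'   all traces; default is one depth per trace.
#' @param bg_dim Background dimensionality, fixed (not fitted), in (2, 3.5].
#' @param r_grid Distance grid used to discretise P(r) during fitting.
#' @param r0_bounds,sigma_bounds Box constraints on centers and widths,
#'   Angstrom.
#' @param maxiter Maximum Levenberg-Marquardt iterations per restart.
#' @return A \code{fit_options} object.
#' @export
fit_options <- function(k_max = 4L, criterion = c("AICc", "BIC"), n_restarts = 8L,
                        seed = 1L, share_widths = TRUE, share_depth = FALSE,
                        bg_dim = 3, r_grid = default_r_grid(),
                        r0_bounds = c(15, 90), sigma_bounds = c(0.5, 15),
                        maxiter = 200L) {
  criterion <- match.arg(criterion)
  stopifnot(k_max >= 1L, n_restarts >= 1L, bg_dim > 2, bg_dim <= 3.5,
            length(r0_bounds) == 2L, length(sigma_bounds) == 2L)
  structure(list(k_max = as.integer(k_max), criterion = criterion,
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 share_widths = share_widths, share_depth = share_depth,
                 bg_dim = bg_dim, r_grid = r_grid, r0_bounds = r0_bounds,
                 sigma_bounds = sigma_bounds, maxiter = as.integer(maxiter)),
            class = "fit_options")
}

# ---- transforms ------------------------------------------------------------

box_tr  <- function(x, lo, hi) lo + (hi - lo) * plogis(x)
box_inv <- function(v, lo, hi) {
  v <- pmin(pmax(v, lo + 1e-9 * (hi - lo)), hi - 1e-9 * (hi - lo))
  qlogis((v - lo) / (hi - lo))
}
box_grad <- function(v, lo, hi) (v - lo) * (hi - v) / (hi - lo)

softmax0 <- function(z) {         # amplitudes from k-1 logits, baseline first
  e <- exp(c(0, z) - max(0, z))
  e / sum(e)
}
amp_logits <- function(a) {
  a <- pmax(a, 1e-12); a <- a / sum(a)
  log(a[-1] / a[1])
}

# ---- parameter map ---------------------------------------------------------

build_pmap <- function(k, cond_labels, trace_cond, opts) {
  C <- length(cond_labels); J <- length(trace_cond)
  idx <- 0L
  nxt <- function(n) { out <- idx + seq_len(n); idx <<- idx + n; out }
  pm <- list(k = k, C = C, J = J, cond = trace_cond, cond_labels = cond_labels,
             share_widths = opts$share_widths, share_depth = opts$share_depth)
  pm$i_r0 <- nxt(k)
  pm$i_sig <- if (opts$share_widths) matrix(nxt(k), k, 1) else matrix(nxt(k * C), k, C)
  pm$i_amp <- if (k > 1L) lapply(seq_len(C), function(cc) nxt(k - 1L)) else NULL
  pm$i_depth <- if (opts$share_depth) rep(nxt(1L), J) else nxt(J)
  pm$i_bg <- nxt(J)
  pm$i_scale <- nxt(J)
  pm$npar <- idx
  pm$par_names <- {
    nm <- character(idx)
    nm[pm$i_r0] <- sprintf("r0_%d", seq_len(k))
    if (opts$share_widths) nm[pm$i_sig] <- sprintf("sigma_%d", seq_len(k))
    else for (cc in seq_len(C))
      nm[pm$i_sig[, cc]] <- sprintf("sigma_%d.%s", seq_len(k), cond_labels[cc])
    if (k > 1L) for (cc in seq_len(C))
      nm[pm$i_amp[[cc]]] <- sprintf("ampl_%d.%s", 2:k, cond_labels[cc])
    nm[unique(pm$i_depth)] <- if (opts$share_depth) "depth"
      else sprintf("depth.%d", seq_len(J))
    nm[pm$i_bg] <- sprintf("bg_rate.%d", seq_len(J))
    nm[pm$i_scale] <- sprintf("scale.%d", seq_len(J))
    nm
  }
  pm
}

unpack_pars <- function(x, pm, opts) {
  k <- pm$k; C <- pm$C
  r0 <- box_tr(x[pm$i_r0], opts$r0_bounds[1], opts$r0_bounds[2])
  sig <- matrix(box_tr(x[pm$i_sig], opts$sigma_bounds[1], opts$sigma_bounds[2]),
                k, ncol(pm$i_sig))
  amps <- matrix(1, C, k)
  if (k > 1L) for (cc in seq_len(C)) amps[cc, ] <- softmax0(x[pm$i_amp[[cc]]])
  rownames(amps) <- pm$cond_labels
  depth <- plogis(x[pm$i_depth])
  bg <- exp(x[pm$i_bg])
  scale <- exp(x[pm$i_scale])
  list(r0 = r0, sigma = sig, amps = amps, depth = depth, bg = bg, scale = scale,
       dr0dx = box_grad(r0, opts$r0_bounds[1], opts$r0_bounds[2]),
       dsigdx = matrix(box_grad(sig, opts$sigma_bounds[1], opts$sigma_bounds[2]),
                       k, ncol(sig)),
       ddepthdx = depth * (1 - depth))
}

# ---- data preparation ------------------------------------------------------

# kernel matrices depend only on the grids, so cache them per (t, r) pair
.kernel_cache <- new.env(parent = emptyenv())

kernel_matrix_cached <- function(t, r) {
  key <- paste(c(length(t), sprintf("%.12g", range(t)), sprintf("%.12g", t[2] - t[1]),
                 length(r), sprintf("%.12g", range(r))), collapse = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit) && isTRUE(all.equal(hit$t, t)) && isTRUE(all.equal(hit$r, r)))
    return(hit$K)
  K <- kernel_matrix(t, r)
  .kernel_cache[[key]] <- list(t = t, r = r, K = K)
  K
}

prepare_fit_data <- function(traces, opts) {
  stopifnot(length(traces) >= 1L)
  lapply(traces, function(tr) stopifnot(inherits(tr, "deer_trace")))
  pair <- unique(vapply(traces, `[[`, character(1), "pair"))
  if (length(pair) != 1L)
    stop(sprintf("all traces must share one pair label; got: %s",
                 paste(pair, collapse = ", ")))
  conds <- vapply(traces, `[[`, character(1), "condition")
  cond_labels <- unique(conds)
  trace_cond <- match(conds, cond_labels)

  rg <- opts$r_grid
  w <- trapz_weights(rg)
  keys <- vapply(traces, function(tr)
    paste(sprintf("%.12g", tr$t), collapse = ","), character(1))
  ukeys <- unique(keys)
  grids <- lapply(ukeys, function(kk) {
    t <- traces[[match(kk, keys)]]$t
    list(t = t, K = kernel_matrix_cached(t, rg))
  })
  gamma <- opts$bg_dim / 3
  tlist <- lapply(seq_along(traces), function(j) {
    tr <- traces[[j]]
    sg <- tr$noise_sigma
    if (is.null(sg)) sg <- estimate_noise(tr)
    sg <- max(sg, 1e-10)
    list(t = tr$t, v = tr$v, grid_id = match(keys[j], ukeys),
         tpow = tr$t^gamma, wres = 1 / sg, sigma = sg, n = length(tr$t))
  })
  list(pair = pair, cond_labels = cond_labels, trace_cond = trace_cond,
       r_grid = rg, w = w, grids = grids, traces = tlist,
       n_obs = sum(vapply(tlist, `[[`, integer(1), "n")))
}

# ---- model + jacobian evaluation -------------------------------------------

eval_model <- function(x, pm, dat, opts, need_jac = FALSE) {
  th <- unpack_pars(x, pm, opts)
  k <- pm$k
  rg <- dat$r_grid; w <- dat$w
  nsc <- ncol(pm$i_sig)

  dens <- vector("list", nsc)
  for (sc in seq_len(nsc)) {
    G <- matrix(0, length(rg), k); dGdr0 <- G; dGds <- G
    for (i in seq_len(k)) {
      sgi <- th$sigma[i, sc]
      z <- (rg - th$r0[i]) / sgi
      g <- dnorm(rg, th$r0[i], sgi)
      G[, i] <- g
      if (need_jac) {
        dGdr0[, i] <- g * z / sgi
        dGds[, i] <- g * (z^2 - 1) / sgi
      }
    }
    N <- colSums(w * G)
    N[N <= 0] <- .Machine$double.xmin
    Ghat <- sweep(G, 2, N, "/")
    out <- list(Ghat = Ghat)
    if (need_jac) {
      dNr0 <- colSums(w * dGdr0); dNs <- colSums(w * dGds)
      out$dHr0 <- sweep(dGdr0, 2, N, "/") - sweep(Ghat, 2, dNr0 / N, "*")
      out$dHs  <- sweep(dGds, 2, N, "/") - sweep(Ghat, 2, dNs / N, "*")
    }
    dens[[sc]] <- out
  }

  ff <- vector("list", length(dat$grids))
  for (g in seq_along(dat$grids)) {
    K <- dat$grids[[g]]$K
    ff[[g]] <- lapply(dens, function(dd) {
      out <- list(f = K %*% (w * dd$Ghat))
      if (need_jac) {
        out$dfr0 <- K %*% (w * dd$dHr0)
        out$dfs  <- K %*% (w * dd$dHs)
      }
      out
    })
  }

  res <- numeric(dat$n_obs)
  if (need_jac) Jm <- matrix(0, dat$n_obs, pm$npar)
  models <- vector("list", pm$J)
  pos <- 0L
  for (j in seq_len(pm$J)) {
    tr <- dat$traces[[j]]
    cc <- pm$cond[j]
    sc <- if (pm$share_widths) 1L else cc
    fb <- ff[[tr$grid_id]][[sc]]
    a <- th$amps[cc, ]
    Fv <- as.vector(fb$f %*% a)
    B <- exp(-th$bg[j] * tr$tpow)
    D <- th$depth[j]; V0 <- th$scale[j]
    mod <- V0 * B * (1 - D * (1 - Fv))
    models[[j]] <- mod
    idx <- pos + seq_len(tr$n); pos <- pos + tr$n
    res[idx] <- (tr$v - mod) * tr$wres
    if (need_jac) {
      core <- V0 * B * D * tr$wres
      for (i in seq_len(k)) {
        Jm[idx, pm$i_r0[i]] <- -core * a[i] * fb$dfr0[, i] * th$dr0dx[i]
        Jm[idx, pm$i_sig[i, sc]] <- -core * a[i] * fb$dfs[, i] * th$dsigdx[i, sc]
      }
      if (k > 1L) {
        ia <- pm$i_amp[[cc]]
        for (l in seq_len(k - 1L)) {
          da <- -a * a[l + 1L]; da[l + 1L] <- da[l + 1L] + a[l + 1L]
          Jm[idx, ia[l]] <- -core * as.vector(fb$f %*% da)
        }
      }
      Jm[idx, pm$i_depth[j]] <- Jm[idx, pm$i_depth[j]] -
        V0 * B * (Fv - 1) * th$ddepthdx[j] * tr$wres
      Jm[idx, pm$i_bg[j]] <- tr$tpow * mod * th$bg[j] * tr$wres
      Jm[idx, pm$i_scale[j]] <- -mod * tr$wres
    }
  }
  out <- list(res = res, models = models, theta = th)
  if (need_jac) out$jac <- Jm
  out
}

# ---- multistart initialisation ---------------------------------------------

# radical-inverse (van der Corput) sequence in the given prime base
radical_inverse <- function(i, base) {
  out <- numeric(length(i))
  f <- 1 / base
  i <- as.integer(i)
  while (any(i > 0L)) {
    out <- out + f * (i %% base)
    i <- i %/% base
    f <- f / base
  }
  out
}

halton_matrix <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (dim > length(primes)) stop("too many Halton dimensions")
  vapply(seq_len(dim), function(d) radical_inverse(seq_len(n), primes[d]),
         numeric(n))
}

make_starts <- function(pm, dat, opts) {
  k <- pm$k; n <- opts$n_restarts
  set.seed(opts$seed)
  H <- matrix(halton_matrix(n, k), nrow = n)
  shift <- matrix(runif(k), n, k, byrow = TRUE)
  centers <- 25 + 40 * ((H + shift) %% 1)
  centers <- t(apply(centers, 1L, sort))
  centers <- matrix(centers, nrow = n)

  starts <- matrix(0, n, pm$npar)
  for (s in seq_len(n)) {
    x <- numeric(pm$npar)
    x[pm$i_r0] <- box_inv(centers[s, ], opts$r0_bounds[1], opts$r0_bounds[2])
    x[pm$i_sig] <- box_inv(3, opts$sigma_bounds[1], opts$sigma_bounds[2])
    if (k > 1L) for (cc in seq_len(pm$C)) x[pm$i_amp[[cc]]] <- 0
    for (j in seq_len(pm$J)) {
      tr <- dat$traces[[j]]
      v1 <- tr$v[1]
      sc0 <- if (is.finite(v1) && v1 > 0) v1 else max(abs(tr$v))
      dep0 <- 1 - min(tr$v) / sc0
      dep0 <- min(max(dep0, 0.05), 0.9)
      x[pm$i_depth[j]] <- qlogis(dep0)
      x[pm$i_bg[j]] <- log(0.05)
      x[pm$i_scale[j]] <- log(sc0)
    }
    starts[s, ] <- x
  }
  starts
}

criteria_values <- function(ssr, p, n) {
  aic <- ssr + 2 * p
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else Inf
  c(AICc = aicc, BIC = ssr + p * log(n))
}

# ---- main fitting function -------------------------------------------------

#' Global fit of DEER traces with a shared Gaussian mixture
#'
#' Simultaneously fits all traces (grouped by their condition labels) with a
#' sum-of-Gaussians distance distribution whose centers and widths are
#' shared across conditions while each condition carries its own amplitude
#' simplex; every trace has its own modulation depth, background rate and
#' amplitude scale. The weighted residual sum of squares
#' \eqn{\sum_j \sum_t [(v - V_{model}) / \sigma_j]^2} is minimised by
#' multistart Levenberg-Marquardt with an analytic Jacobian.
#'
#' @param traces List of [deer_trace()] objects sharing one pair label.
#' @param k Number of Gaussian components.
#' @param options A [fit_options()] object.
#' @return A \code{deer_global_fit} object with components
#'   \describe{
#'     \item{spec}{fitted [mixture_spec()] (canonically ordered)}
#'     \item{nuisances}{per-trace [trace_nuisance()] estimates}
#'     \item{covariance}{free-parameter covariance (internal scale), scaled
#'       by the reduced chi-square}
#'     \item{chi2_red}{reduced chi-square}
#'     \item{criteria}{AICc and BIC values}
#'     \item{converged}{logical; optimizer failures are flagged, not silent}
#'   }
#' @seealso [select_components()], [confidence_band()], [fit_options()]
#' @examples
#' sc <- make_scenario(demo_scenario(n_points = 120, snr = 80))
#' fit <- deer_global_fit(sc$traces, k = 2,
#'                        options = fit_options(n_restarts = 2, seed = 7))
#' fit
#' @export
deer_global_fit <- function(traces, k = 2L, options = fit_options()) {
  stopifnot(inherits(options, "fit_options"), k >= 1L)
  dat <- prepare_fit_data(traces, options)
  pm <- build_pmap(as.integer(k), dat$cond_labels, dat$trace_cond, options)
  starts <- make_starts(pm, dat, options)

  run_lm <- function(x0) tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = x0,
      fn = function(p) eval_model(p, pm, dat, options)$res,
      jac = function(p) eval_model(p, pm, dat, options, need_jac = TRUE)$jac,
      control = minpack.lm::nls.lm.control(
        maxiter = options$maxiter, ftol = 1e-10, ptol = 1e-10))),
    error = function(e) e)

  best <- NULL
  failures <- character(0)
  for (s in seq_len(nrow(starts))) {
    ans <- run_lm(starts[s, ])
    if (inherits(ans, "error")) { failures <- c(failures, conditionMessage(ans)); next }
    if (!is.finite(ans$deviance)) { failures <- c(failures, "non-finite deviance"); next }
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  if (!is.null(best) && !best$info %in% c(1, 2, 3, 4)) {
    polish <- run_lm(best$par)   # finish a maxiter-terminated restart
    if (!inherits(polish, "error") && is.finite(polish$deviance) &&
        polish$deviance <= best$deviance) best <- polish
  }

  if (is.null(best)) {
    return(structure(list(converged = FALSE, messages = failures, k = k,
                          pair = dat$pair, conditions = dat$cond_labels,
                          options = options),
                     class = "deer_global_fit"))
  }

  # canonical component order: ascending r0, ties by sigma
  th <- unpack_pars(best$par, pm, options)
  ord <- order(th$r0, th$sigma[, 1])
  x <- best$par
  if (!identical(ord, seq_len(pm$k))) {
    x[pm$i_r0] <- box_inv(th$r0[ord], options$r0_bounds[1], options$r0_bounds[2])
    for (sc in seq_len(ncol(pm$i_sig)))
      x[pm$i_sig[, sc]] <- box_inv(th$sigma[ord, sc],
                                   options$sigma_bounds[1], options$sigma_bounds[2])
    if (pm$k > 1L) for (cc in seq_len(pm$C))
      x[pm$i_amp[[cc]]] <- amp_logits(th$amps[cc, ord])
  }

  ev <- eval_model(x, pm, dat, options, need_jac = TRUE)
  th <- ev$theta
  ssr <- sum(ev$res^2)
  dof <- dat$n_obs - pm$npar
  chi2_red <- if (dof > 0) ssr / dof else NA_real_
  JtJ <- crossprod(ev$jac)
  cov_x <- tryCatch(chi2_red * chol2inv(chol(JtJ)), error = function(e) NULL)
  if (is.null(cov_x)) {
    warning("near-singular parameter information; using pseudo-inverse covariance")
    cov_x <- chi2_red * pracma::pinv(JtJ)
  }
  cov_x <- (cov_x + t(cov_x)) / 2
  dimnames(cov_x) <- list(pm$par_names, pm$par_names)

  spec <- if (options$share_widths)
    mixture_spec(th$r0, th$sigma[, 1],
                 matrix(th$amps, pm$C, pm$k, dimnames = list(dat$cond_labels, NULL)))
  else NULL
  nuis <- lapply(seq_len(pm$J), function(j)
    trace_nuisance(min(max(th$depth[j], 1e-8), 1 - 1e-8), th$bg[j],
                   options$bg_dim, th$scale[j]))
  resid_raw <- lapply(seq_len(pm$J), function(j)
    dat$traces[[j]]$v - ev$models[[j]])

  structure(list(
    spec = spec, sigma_by_condition = if (!options$share_widths) th$sigma else NULL,
    amplitudes = th$amps, r0 = th$r0,
    nuisances = nuis, covariance = cov_x, x_opt = x, pmap = pm,
    chi2_red = chi2_red, deviance = ssr,
    criteria = criteria_values(ssr, pm$npar, dat$n_obs),
    n_obs = dat$n_obs, n_params = pm$npar,
    residuals = resid_raw, fitted_signals = ev$models,
    noise_sigmas = vapply(dat$traces, `[[`, numeric(1), "sigma"),
    traces = traces, r_grid = options$r_grid, pair = dat$pair,
    conditions = dat$cond_labels, trace_cond = dat$trace_cond,
    k = as.integer(k), options = options,
    converged = (best$info %in% c(1, 2, 3, 4, 6, 7) ||
                 (best$info == -1 && is.finite(chi2_red))) && is.finite(ssr),
    optim_info = best$info),
    class = "deer_global_fit")
}

# density of the fitted P(r) for one condition on an arbitrary grid,
# as a function of the free-parameter vector (used by confidence bands)
fit_density <- function(fit, condition, r, x = fit$x_opt) {
  pm <- fit$pmap; opts <- fit$options
  cc <- match(condition, fit$conditions)
  if (is.na(cc)) stop(sprintf("unknown condition '%s'", condition))
  th <- unpack_pars(x, pm, opts)
  sc <- if (pm$share_widths) 1L else cc
  G <- component_densities(r, th$r0, th$sigma[, sc])
  as.vector(G %*% th$amps[cc, ])
}

#' Fitted distance distribution for one condition
#'
#' @param fit A converged \code{deer_global_fit}.
#' @param condition Condition label.
#' @param r Distance grid (defaults to the fit grid).
#' @return A \code{distance_distribution} (list with \code{r}, \code{p}).
#' @export
distance_distribution <- function(fit, condition, r = fit$r_grid) {
  stopifnot(inherits(fit, "deer_global_fit"), isTRUE(fit$converged))
  structure(list(r = r, p = fit_density(fit, condition, r)),
            class = "distance_distribution")
}
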