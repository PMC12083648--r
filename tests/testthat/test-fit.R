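# Global fitting: parameter recovery, weighting, determinism, Jacobian.

test_that("analytic Jacobian matches central finite differences", {
  sc <- make_scenario(demo_scenario(conditions = c("apo", "PF-543"),
                                    amplitude_matrix = rbind(c(0.3, 0.7), c(0.8, 0.2)),
                                    n_points = 80, seed = 2))
  opts <- quick_opts()
  dat <- deerstate:::prepare_fit_data(sc$traces, opts)
  pm <- deerstate:::build_pmap(2L, dat$cond_labels, dat$trace_cond, opts)
  x <- deerstate:::make_starts(pm, dat, opts)[1, ] + 0.05
  ev <- deerstate:::eval_model(x, pm, dat, opts, need_jac = TRUE)
  h <- 1e-6
  Jnum <- vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (deerstate:::eval_model(xp, pm, dat, opts)$res -
     deerstate:::eval_model(xm, pm, dat, opts)$res) / (2 * h)
  }, numeric(dat$n_obs))
  expect_lt(max(abs(ev$jac - Jnum)) / max(1, max(abs(Jnum))), 1e-5)
})

test_that("a single-condition global fit reduces to the individual fit", {
  sc <- make_scenario(demo_scenario(conditions = "apo",
                                    amplitude_matrix = rbind(c(0.3, 0.7)),
                                    seed = 4))
  opts <- quick_opts(seed = 9)
  res <- compare_individual_global(sc$traces, opts, k = 2)
  expect_equal(nrow(res), 1L)
  expect_lt(res$tv, 1e-6)
  g <- attr(res, "global"); ind <- attr(res, "individual")[[1]]
  expect_lt(abs(g$deviance - ind$deviance) / ind$deviance, 1e-6)
})

test_that("the two-component five-condition ensemble is recovered", {
  # sanity-scale recovery (a few seeds, loose bounds); the 20-replicate study
  # at the tight tolerances runs in the acceptance suite
  for (s in 1:4) {
    sc <- make_scenario(demo_scenario(seed = 2000 + 10 * s))
    fit <- deer_global_fit(sc$traces, 2, fit_options(n_restarts = 4, seed = s))
    expect_true(fit$converged)
    truth_a <- sc$truth$spec$amplitudes
    expect_lt(max(abs(fit$r0 - c(40, 55))), 1)
    expect_lt(max(abs(fit$amplitudes - truth_a)), 0.1)
    for (cc in seq_len(nrow(fit$amplitudes))) expect_simplex(fit$amplitudes[cc, ])
    expect_equal(fit$r0, sort(fit$r0))
  }
})

test_that("reduced chi-square is near one at the true model", {
  chis <- vapply(1:6, function(s) {
    sc <- make_scenario(demo_scenario(seed = 300 + s))
    deer_global_fit(sc$traces, 2, quick_opts(seed = s))$chi2_red
  }, numeric(1))
  expect_gt(median(chis), 0.8)
  expect_lt(median(chis), 1.2)
})

test_that("pure-background traces yield near-zero fitted depth", {
  spec <- mixture_spec(40, 3, matrix(1, 2, 1, dimnames = list(c("a", "b"), NULL)))
  t <- seq(0, 4, length.out = 150)
  traces <- lapply(c("a", "b"), function(cd) {
    mu <- exp(-0.08 * t)
    set.seed(match(cd, c("a", "b")))
    deer_trace(t, mu + rnorm(150, 0, 0.01), condition = cd, noise_sigma = 0.01)
  })
  fit <- deer_global_fit(traces, 1, quick_opts(seed = 2))
  expect_true(fit$converged)
  for (nu in fit$nuisances) expect_lt(nu$depth, 0.02)
})

test_that("fits are deterministic given the seed", {
  sc <- make_scenario(demo_scenario(seed = 7))
  f1 <- deer_global_fit(sc$traces, 2, quick_opts(seed = 42))
  f2 <- deer_global_fit(sc$traces, 2, quick_opts(seed = 42))
  expect_identical(f1$x_opt, f2$x_opt)
  expect_identical(f1$chi2_red, f2$chi2_red)
  expect_identical(coef(f1), coef(f2))
})

test_that("fit methods expose coherent views of the model", {
  sc <- make_scenario(demo_scenario(seed = 11))
  fit <- deer_global_fit(sc$traces, 2, quick_opts(seed = 1))
  cf <- coef(fit)
  expect_true(all(c("r0_1", "sigma_2", "ampl_1.apo", "depth.1") %in% names(cf)))
  V <- vcov(fit)
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_true(all(diag(V) >= 0))
  expect_equal(dim(V), c(fit$n_params, fit$n_params))

  prs <- predict(fit, "signal", condition = "apo")
  expect_equal(prs, fit$fitted_signals[[1]], tolerance = 1e-9)
  dd <- predict(fit, "distribution", condition = "PF-543")
  expect_equal(trapz(dd$r, dd$p), 1, tolerance = 1e-6)

  res <- residuals(fit)
  expect_equal(length(res), 5L)
  expect_equal(res[[1]], sc$traces[[1]]$v - fit$fitted_signals[[1]])

  sim <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sim, 2L)
  expect_s3_class(sim[[1]][[3]], "deer_trace")
  sim_rep <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(sim[[2]][[1]]$v, sim_rep[[2]][[1]]$v)

  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); plot(fit, which = "traces"); grDevices::dev.off()
  expect_true(file.exists(tf))
  expect_output(print(summary(fit)), "nuisance")
})

test_that("width-sharing and depth-sharing flags change the parameterisation", {
  sc <- make_scenario(demo_scenario(conditions = c("apo", "PF-543"),
                                    amplitude_matrix = rbind(c(0.3, 0.7), c(0.8, 0.2)),
                                    n_points = 120, seed = 55))
  shared <- deer_global_fit(sc$traces, 2, quick_opts(seed = 1))
  f_w <- deer_global_fit(sc$traces, 2, quick_opts(seed = 1, share_widths = FALSE))
  f_d <- deer_global_fit(sc$traces, 2, quick_opts(seed = 1, share_depth = TRUE))
  expect_true(f_w$converged && f_d$converged)
  expect_equal(dim(f_w$sigma_by_condition), c(2L, 2L))
  expect_equal(f_w$n_params, shared$n_params + 2L)      # one extra width pair
  expect_equal(f_d$n_params, shared$n_params - 1L)      # one shared depth
  depths <- vapply(f_d$nuisances, `[[`, numeric(1), "depth")
  expect_equal(depths[1], depths[2], tolerance = 1e-12)
  # both variants still recover the generating centers
  expect_lt(max(abs(f_w$r0 - c(40, 55))), 1.5)
  expect_lt(max(abs(f_d$r0 - c(40, 55))), 1.5)
})

test_that("mismatched pair labels are refused", {
  sc <- make_scenario(demo_scenario(seed = 3))
  sc$traces[[2]]$pair <- "other"
  expect_error(deer_global_fit(sc$traces, 2, quick_opts()), "pair")
})
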