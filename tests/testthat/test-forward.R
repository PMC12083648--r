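test_that("dipolar frequency follows the r^-3 law", {
  expect_equal(dipolar_frequency(10), 52.04)
  expect_equal(dipolar_frequency(20), 52.04 / 8)
  expect_lt(dipolar_frequency(30), dipolar_frequency(20))
  expect_error(dipolar_frequency(0), "positive")
  expect_error(dipolar_frequency(-5), "positive")
})

test_that("kernel matches the 10k-node quadrature oracle and stays bounded", {
  expect_equal(kernel_value(0, 20), 1.0)
  expect_equal(kernel_value(0, 77.3), 1.0)
  expect_equal(kernel_value(5, 20), kernel_oracle(5, 20), tolerance = 1e-9)
  expect_lt(abs(kernel_value(50, 30)), 0.05)
  expect_equal(kernel_value(50, 30), kernel_oracle(50, 30), tolerance = 1e-9)

  tt <- seq(0, 8, length.out = 25)
  rr <- seq(15, 80, length.out = 25)
  K <- kernel_matrix(tt, rr)
  Ko <- outer(tt, rr, Vectorize(kernel_oracle))
  expect_lt(max(abs(K - Ko)), 1e-6)
  expect_true(all(abs(K) <= 1 + 1e-12))
  expect_error(kernel_value(-1, 30), "0")
  expect_error(kernel_value(1, 5), "\\[10, 120\\]")
})

test_that("kernel matrix has the right shape and a unit t = 0 row", {
  expect_equal(kernel_matrix(0, c(20, 40)), matrix(1, 1, 2))
  K <- kernel_matrix(seq(0, 3, length.out = 100), seq(15, 85, by = 0.2))
  expect_equal(dim(K), c(100L, 351L))
  expect_equal(K[7, 40], kernel_value(seq(0, 3, length.out = 100)[7],
                                      seq(15, 85, by = 0.2)[40]))
  expect_error(kernel_matrix(numeric(0), 20), "empty")
})

test_that("mixture densities integrate to one and respect the simplex", {
  r <- seq(10, 90, 0.2)
  spec1 <- mixture_spec(40, 3, matrix(1, 1, 1, dimnames = list("apo", NULL)))
  d1 <- evaluate_mixture(spec1, "apo", r)
  expect_equal(r[which.max(d1$p)], 40, tolerance = 0.2)
  expect_equal(trapz(d1$r, d1$p), 1, tolerance = 1e-6)

  spec2 <- mixture_spec(c(40, 55), c(3, 4),
                        matrix(c(0.3, 0.7), 1, dimnames = list("apo", NULL)))
  d2 <- evaluate_mixture(spec2, "apo", r)
  expect_equal(trapz(d2$r, d2$p), 1, tolerance = 1e-6)
  in3s <- d2$r >= 55 - 3 * 4 & d2$r <= 55 + 3 * 4
  # second component's 3-sigma mass plus the first component's tail above 43 A
  want <- 0.7 * (pnorm(3) - pnorm(-3)) + 0.3 * (1 - pnorm((43 - 40) / 3))
  expect_equal(trapz(d2$r[in3s], d2$p[in3s]), want, tolerance = 0.01)

  specd <- mixture_spec(c(40, 55), c(3, 4),
                        matrix(c(1, 0), 1, dimnames = list("apo", NULL)))
  dd <- evaluate_mixture(specd, "apo", r)
  expect_equal(dd$p, d1$p, tolerance = 1e-12)

  expect_error(evaluate_mixture(spec2, "nope", r), "not present")
  expect_error(evaluate_mixture(spec2, "apo", seq(35, 60, 0.2)), "span")
  expect_error(mixture_spec(c(40, 55), c(3, 4), rbind(c(0.4, 0.7))), "sum to 1")
})

test_that("components are canonically ordered by center then width", {
  sp <- mixture_spec(c(55, 40), c(4, 3),
                     matrix(c(0.7, 0.3), 1, dimnames = list("apo", NULL)))
  expect_equal(sp$r0, c(40, 55))
  expect_equal(as.numeric(sp$amplitudes), c(0.3, 0.7))
  tie <- mixture_spec(c(40, 40), c(5, 2),
                      matrix(c(0.6, 0.4), 1, dimnames = list("apo", NULL)))
  expect_equal(tie$sigma, c(2, 5))
})

test_that("signal model obeys its boundary and linearity properties", {
  nu <- trace_nuisance(depth = 0.35, bg_rate = 0.05, scale = 1.3)
  spec <- mixture_spec(c(40, 55), c(3, 4),
                       matrix(c(0.3, 0.7), 1, dimnames = list("apo", NULL)))
  t <- seq(0, 4, length.out = 100)

  # t = 0 returns exactly V0
  expect_equal(model_signal(spec, nu, "apo", t)[1], 1.3)

  # depth -> 0 limit leaves the pure background
  nu0 <- trace_nuisance(depth = 1e-12, bg_rate = 0.1, scale = 1)
  expect_equal(model_signal(spec, nu0, "apo", 2), exp(-0.2), tolerance = 1e-9)

  # narrow component reduces to the kernel at its center
  sharp <- mixture_spec(40, 0.5, matrix(1, 1, 1, dimnames = list("apo", NULL)))
  nuf <- trace_nuisance(depth = 1 - 1e-12, bg_rate = 0, scale = 1)
  tt <- seq(0, 3, length.out = 60)
  # a sigma = 0.5 A component is close to, but measurably broader than, a
  # delta at r0: the quadrature oracle puts the peak difference at 0.021
  # (Gaussian frequency spread damping the dipolar oscillation by t = 3 us)
  expect_lt(max(abs(model_signal(sharp, nuf, "apo", tt) - kernel_value(tt, 40))),
            0.03)

  # form factor is linear in the amplitudes
  s1 <- mixture_spec(40, 3, matrix(1, 1, dimnames = list("apo", NULL)))
  s2 <- mixture_spec(55, 4, matrix(1, 1, dimnames = list("apo", NULL)))
  mix <- mixture_spec(c(40, 55), c(3, 4),
                      matrix(c(0.3, 0.7), 1, dimnames = list("apo", NULL)))
  f <- function(sp) model_signal(sp, nuf, "apo", tt)
  expect_equal(f(mix), 0.3 * f(s1) + 0.7 * f(s2), tolerance = 1e-10)

  # reordering the input components does not change the signal
  mix_r <- mixture_spec(c(55, 40), c(4, 3),
                        matrix(c(0.7, 0.3), 1, dimnames = list("apo", NULL)))
  expect_equal(model_signal(mix_r, nu, "apo", t), model_signal(mix, nu, "apo", t))
})

test_that("type constructors enforce their bounds", {
  expect_error(gauss_component(10, 3), "\\[15, 90\\]")
  expect_error(gauss_component(40, 0.2), "\\[0.5, 15\\]")
  expect_error(trace_nuisance(0, 0.1), "\\(0, 1\\)")
  expect_error(trace_nuisance(0.3, -1), ">= 0")
  expect_error(trace_nuisance(0.3, 0.1, bg_dim = 4), "\\(2, 3.5\\]")
  expect_error(trace_nuisance(0.3, 0.1, scale = 0), "> 0")
  expect_error(deer_trace(1:10, 1:10), "16")
  expect_error(deer_trace(c(0, 1, 1, seq(2, 20)), rep(1, 22)), "increasing")
  expect_error(deer_trace(seq(5, 24), rep(1, 20)), "first time point")
})
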