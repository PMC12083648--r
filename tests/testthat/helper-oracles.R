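# Independent oracles and small fixture builders used across tests.

# 10,000-node quadrature oracle for the powder-averaged dipolar kernel:
# composite Gauss-Legendre, 500 panels x 20 nodes on u in [0, 1]
gl_nodes_10k <- local({
  g20 <- pracma::gaussLegendre(20, 0, 1)
  panels <- 500
  list(x = as.vector(outer(g20$x / panels, (seq_len(panels) - 1) / panels, "+")),
       w = rep(g20$w / panels, panels))
})

kernel_oracle <- function(t, r) {
  nu <- 52.04 / (r / 10)^3
  sum(gl_nodes_10k$w * cos((1 - 3 * gl_nodes_10k$x^2) * 2 * pi * nu * t))
}

# exhaustive double-loop minimum cross distance (plain double additions, so
# the comparison with the vectorized path is exact, not merely close)
min_dist_oracle <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d2 <- (A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2 + (A[i, 3] - B[j, 3])^2
    if (d2 < best) best <- d2
  }
  sqrt(best)
}

# trapezoid integral
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# random small trajectory: two chains of point atoms
random_trajectory <- function(n_a = 8, n_b = 12, n_frames = 5, seed = 1) {
  set.seed(seed)
  n <- n_a + n_b
  atoms <- data.frame(serial = seq_len(n),
                      name = rep(c("A1", "B1"), c(n_a, n_b)),
                      resname = rep(c("RESA", "RESB"), c(n_a, n_b)),
                      resid = seq_len(n),
                      chain = rep(c("A", "B"), c(n_a, n_b)),
                      stringsAsFactors = FALSE)
  coords <- array(rnorm(n * 3 * n_frames, sd = 6), c(n, 3, n_frames))
  md_trajectory(atoms, coords)
}

# compact fit options for tests
quick_opts <- function(seed = 1, ...) {
  fit_options(n_restarts = 2, seed = seed, ...)
}

expect_simplex <- function(a, tol = 1e-9) {
  expect_true(all(a >= -tol))
  expect_lt(abs(sum(a) - 1), tol)
}
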