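# MD contact statistics against exhaustive oracles.

two_point_traj <- function(frames) {
  # frames: list of 2-row coordinate matrices (atom A then atom B)
  atoms <- data.frame(serial = 1:2, name = c("P1", "N1"), resname = c("ARG", "ASP"),
                      resid = c(225L, 162L), chain = "P", stringsAsFactors = FALSE)
  coords <- array(0, c(2, 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  md_trajectory(atoms, coords)
}

test_that("minimum distances follow the geometry and the min rule", {
  tj <- two_point_traj(list(rbind(c(0, 0, 0), c(3, 4, 0))))
  expect_equal(min_distance_series(tj, "resid 225", "resid 162"), 5.0)

  atoms <- data.frame(serial = 1:3, name = c("A1", "B1", "B2"),
                      resname = "RES", resid = c(1L, 2L, 2L), chain = "X",
                      stringsAsFactors = FALSE)
  coords <- array(0, c(3, 3, 1))
  coords[1, , 1] <- c(0, 0, 0); coords[2, , 1] <- c(6, 0, 0); coords[3, , 1] <- c(0, 4, 0)
  tj2 <- md_trajectory(atoms, coords)
  expect_equal(min_distance_series(tj2, "resid 1", "resid 2"), 4.0)

  expect_error(min_distance_series(tj2, "resid 1", "resid 1,2"), "disjoint")
  expect_error(min_distance_series(tj2, "resid 7", "resid 2"), "resid 7")
})

test_that("minimum distance equals the exhaustive double-loop oracle exactly", {
  for (s in 1:10) {
    tj <- random_trajectory(n_a = 9, n_b = 14, n_frames = 4, seed = s)
    got <- min_distance_series(tj, "chain A", "chain B")
    ia <- which(tj$atoms$chain == "A"); ib <- which(tj$atoms$chain == "B")
    want <- vapply(1:4, function(f)
      min_dist_oracle(tj$coords[ia, , f], tj$coords[ib, , f]), numeric(1))
    expect_identical(got, want)
    # symmetry in the two selections
    expect_identical(got, min_distance_series(tj, "chain B", "chain A"))
  }
})

test_that("salt-bridge contacts are boundary-inclusive with fraction = mean", {
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  tj <- two_point_traj(lapply(c(4.4, 4.6, 4.5), mk))
  cs <- salt_bridge_series(tj, "resid 225", "resid 162")
  expect_equal(cs$cutoff, 4.5)
  expect_equal(cs$contact, c(TRUE, FALSE, TRUE))
  expect_equal(cs$fraction, 2 / 3)

  tj2 <- two_point_traj(lapply(c(3.0, 5.0, 4.0), mk))
  expect_equal(salt_bridge_series(tj2, "resid 225", "resid 162")$fraction, 2 / 3)

  tj3 <- two_point_traj(lapply(c(6, 7, 8), mk))
  expect_equal(salt_bridge_series(tj3, "resid 225", "resid 162")$fraction, 0)
})

test_that("lipid contact percentages recover scripted truth and warn on unknowns", {
  cfg <- membrane_config(
    n_frames = 100,
    contact_script = list(POPS = list(`225` = 1:30)),
    seed = 3)
  gen <- make_membrane_trajectory(cfg)
  lp <- lipid_contact_percentages(gen$trajectory, "chain P and resid 225",
                                  c("POPS", "CHL1"))
  expect_equal(lp$percent[lp$lipid_type == "POPS"], 30.0)
  expect_equal(lp$percent[lp$lipid_type == "CHL1"], 0.0)
  expect_warning(
    out <- lipid_contact_percentages(gen$trajectory, "resid 225 and chain P",
                                     c("NOPE")),
    "NOPE")
  expect_equal(out$percent, 0)
  expect_error(lipid_contact_percentages(gen$trajectory, "chain P", character(0)),
               "nonempty")
})

test_that("lipid percentages equal a brute-force per-frame oracle exactly", {
  for (s in 1:5) {
    cfg <- membrane_config(n_frames = 12, n_lipids = 20,
                           lipid_ratio = c(POPS = 1, POPC = 1),
                           contact_script = list(POPS = list(`225` = c(2:4, 9))),
                           jitter = 0.5, seed = s)
    gen <- make_membrane_trajectory(cfg)
    tj <- gen$trajectory
    lp <- lipid_contact_percentages(tj, "chain P and resid 225", c("POPS", "POPC"))
    ia <- which(tj$atoms$chain == "P" & tj$atoms$resid == 225)
    for (tp in c("POPS", "POPC")) {
      ib <- which(tj$atoms$resname == tp)
      hits <- vapply(1:12, function(f)
        min_dist_oracle(matrix(tj$coords[ia, , f], ncol = 3),
                        matrix(tj$coords[ib, , f], ncol = 3)) <= 4.0, logical(1))
      expect_identical(lp$percent[lp$lipid_type == tp], 100 * mean(hits))
    }
  }
})

test_that("RMSD is zero for rigid motions and exact for the two-atom stretch", {
  set.seed(8)
  base <- matrix(rnorm(15, sd = 4), 5, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  atoms <- data.frame(serial = 1:5, name = "CA", resname = "GLY", resid = 1:5,
                      chain = "A", stringsAsFactors = FALSE)
  coords <- array(0, c(5, 3, 3))
  coords[, , 1] <- base
  coords[, , 2] <- base                       # identical frame
  coords[, , 3] <- base %*% t(R) + matrix(c(5, -2, 9), 5, 3, byrow = TRUE)
  tj <- md_trajectory(atoms, coords)
  rm <- rmsd_series(tj, "chain A")
  expect_equal(rm[1], 0)
  expect_equal(rm[2], 0, tolerance = 1e-12)
  expect_equal(rm[3], 0, tolerance = 1e-9)    # rigid rotation + translation

  # two-atom stretch: optimal superposition centers the bond
  tj2 <- two_point_traj(list(rbind(c(0, 0, 0), c(2, 0, 0)),
                             rbind(c(0, 0, 0), c(4, 0, 0))))
  expect_equal(rmsd_series(tj2, "chain P"), c(0, 1))

  # coincident selection falls back to translation-only with a warning
  tjc <- two_point_traj(list(rbind(c(1, 1, 1), c(1, 1, 1)),
                             rbind(c(3, 2, 0), c(3, 2, 0))))
  expect_warning(rc <- rmsd_series(tjc, "chain P"), "translation-only")
  expect_equal(rc, c(0, 0))
})

test_that("RMSD series is invariant under a global rigid transform", {
  tj <- random_trajectory(n_a = 10, n_b = 5, n_frames = 6, seed = 4)
  rm0 <- rmsd_series(tj, "chain A")
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  tj2 <- tj
  for (f in 1:6)
    tj2$coords[, , f] <- tj$coords[, , f] %*% t(R) +
      matrix(c(-3, 8, 2), nrow(tj$atoms), 3, byrow = TRUE)
  expect_equal(rmsd_series(tj2, "chain A"), rm0, tolerance = 1e-9)
  expect_equal(rm0[1], 0)
})

test_that("rmsd cross-checks against bio3d on a shared fixture", {
  tj <- random_trajectory(n_a = 12, n_b = 4, n_frames = 5, seed = 6)
  idx <- which(tj$atoms$chain == "A")
  ours <- rmsd_series(tj, "chain A")
  ref <- as.vector(t(tj$coords[idx, , 1]))
  other <- vapply(1:5, function(f) {
    mob <- as.vector(t(tj$coords[idx, , f]))
    bio3d::rmsd(ref, mob, fit = TRUE)
  }, numeric(1))
  expect_equal(ours, other, tolerance = 1e-4)
})

test_that("selection grammar handles and/or/parentheses and bad syntax", {
  tj <- random_trajectory(n_a = 3, n_b = 3, n_frames = 1, seed = 2)
  expect_equal(select_atoms(tj, "chain A or chain B"), 1:6)
  expect_equal(select_atoms(tj, "(resid 1,2 or resid 5) and chain A"), 1:2)
  expect_equal(select_atoms(tj, "name B1 and resname RESB"), 4:6)
  expect_error(select_atoms(tj, "resid 1 and (chain A"), "parenthes")
  expect_error(select_atoms(tj, "bogus 3"), "syntax")
  expect_error(select_atoms(tj, 99), "out of range")
})
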