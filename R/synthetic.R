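# Synthetic-data generators with known ground truth: multi-condition DEER
# ensembles and membrane/protein pseudo-trajectories with scripted contacts.

#' Simulate one noisy DEER trace
#'
#' Evaluates [model_signal()] and adds i.i.d. zero-mean Gaussian noise with
#' standard deviation \code{max(|signal|) / snr}. Deterministic for a given
#' seed; \code{snr = Inf} returns the noiseless model.
#'
#' @inheritParams model_signal
#' @param snr Signal-to-noise ratio (> 0), or \code{Inf} for no noise.
#' @param seed Integer seed.
#' @param pair Spin-pair label for the trace.
#' @return A [deer_trace()] with \code{noise_sigma} recorded.
#' @export
make_trace <- function(spec, nuisance, condition, t, snr = 50, seed = 1L,
                       pair = "pair", r = default_r_grid()) {
  stopifnot(snr > 0)
  mu <- model_signal(spec, nuisance, condition, t, r)
  if (is.infinite(snr)) {
    return(deer_trace(t, mu, condition = condition, pair = pair))
  }
  sg <- max(abs(mu)) / snr
  set.seed(as.integer(seed))
  deer_trace(t, mu + rnorm(length(mu), 0, sg), condition = condition,
             pair = pair, noise_sigma = sg)
}

#' Configuration of a multi-condition DEER scenario
#'
#' @param conditions Character vector of condition labels.
#' @param components Two-column matrix (or coercible) of component
#'   \code{(r0, sigma)} in Angstrom.
#' @param amplitude_matrix Condition x component matrix of simplex rows.
#' @param depth,bg_rate,bg_dim Shared nuisance truth (modulation depth,
#'   background rate in 1/us, background dimensionality).
#' @param t_max Trace length, microseconds.
#' @param n_points Points per trace (>= 64).
#' @param snr Signal-to-noise ratio.
#' @param seed Integer base seed; trace j uses \code{seed + j}.
#' @param pair Spin-pair label.
#' @return A \code{scenario_config} object.
#' @export
scenario_config <- function(conditions, components, amplitude_matrix,
                            depth = 0.35, bg_rate = 0.05, bg_dim = 3,
                            t_max = 4, n_points = 200L, snr = 50,
                            seed = 1L, pair = "T193-M298") {
  components <- matrix(as.numeric(as.matrix(components)), ncol = 2)
  A <- as.matrix(amplitude_matrix)
  if (nrow(A) != length(conditions) || ncol(A) != nrow(components))
    stop("amplitude matrix must be conditions x components")
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-9))
    stop("amplitude rows must lie on the probability simplex")
  if (n_points < 64L) stop("`n_points` must be >= 64")
  if (snr <= 0) stop("`snr` must be > 0")
  rownames(A) <- conditions
  structure(list(conditions = conditions, components = components,
                 amplitude_matrix = A, depth = depth, bg_rate = bg_rate,
                 bg_dim = bg_dim, t_max = t_max, n_points = as.integer(n_points),
                 snr = snr, seed = as.integer(seed), pair = pair),
            class = "scenario_config")
}

#' Demonstration scenario: two shared components, five conditions
#'
#' A generic two-state ensemble in the DEER-sensitive range: components at
#' (40 A, 3 A) and (55 A, 4 A) with the short-distance ("closed")
#' population stepping through 0.3, 0.5, 0.4, 0.7, 0.9 across five
#' biochemical conditions. The centers are deliberately generic defaults,
#' not experimental values.
#'
#' @param ... Overrides passed to [scenario_config()].
#' @return A \code{scenario_config}.
#' @export
demo_scenario <- function(...) {
  closed <- c(0.3, 0.5, 0.4, 0.7, 0.9)
  cfg <- list(conditions = c("apo", "Sph", "MgATP", "MgATP-Sph", "PF-543"),
              components = rbind(c(40, 3), c(55, 4)),
              amplitude_matrix = cbind(closed, 1 - closed),
              depth = 0.35, bg_rate = 0.05, t_max = 4, n_points = 200L,
              snr = 50, seed = 1L)
  do.call(scenario_config, modifyList(cfg, list(...)))
}

#' Two-condition scenario with a rising closed-state population
#'
#' Emulates an inhibitor-style equilibrium shift: the short-distance
#' ("closed") component's population rises from 0.3 to 0.8 between the two
#' conditions.
#'
#' @param ... Overrides passed to [scenario_config()].
#' @return A \code{scenario_config}.
#' @export
shift_scenario <- function(...) {
  cfg <- list(conditions = c("reference", "shifted"),
              components = rbind(c(40, 3), c(55, 4)),
              amplitude_matrix = rbind(c(0.3, 0.7), c(0.8, 0.2)),
              depth = 0.35, bg_rate = 0.05, t_max = 4, n_points = 200L,
              snr = 50, seed = 1L)
  do.call(scenario_config, modifyList(cfg, list(...)))
}

#' Generate a multi-condition DEER ensemble with known truth
#'
#' One trace per condition, all sharing the scenario's Gaussian components
#' with condition-dependent populations. Pure functions of config + seed.
#'
#' @param config A [scenario_config()].
#' @return List with \code{truth} (the generating [mixture_spec()],
#'   nuisance values and config) and \code{traces} (list of
#'   [deer_trace()]).
#' @export
make_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  spec <- mixture_spec(config$components[, 1], config$components[, 2],
                       config$amplitude_matrix)
  nuis <- trace_nuisance(config$depth, config$bg_rate, config$bg_dim, 1)
  t <- seq(0, config$t_max, length.out = config$n_points)
  traces <- lapply(seq_along(config$conditions), function(j)
    make_trace(spec, nuis, config$conditions[j], t, snr = config$snr,
               seed = config$seed + j, pair = config$pair))
  list(truth = list(spec = spec, nuisance = nuis, config = config),
       traces = traces)
}

#' Write a generated scenario to a directory
#'
#' Emits one trace file per condition (the two-column text dialect) and a
#' \code{truth.json} ground-truth file alongside.
#'
#' @param scenario Result of [make_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- scenario$truth$config
  paths <- character(0)
  for (tr in scenario$traces) {
    p <- file.path(dir, sprintf("%s_%s.dat", gsub("[^A-Za-z0-9_-]", "_", tr$pair),
                                gsub("[^A-Za-z0-9_-]", "_", tr$condition)))
    write_trace(tr, p)
    paths <- c(paths, p)
  }
  truth <- list(pair = cfg$pair, conditions = cfg$conditions,
                r0_A = scenario$truth$spec$r0, sigma_A = scenario$truth$spec$sigma,
                amplitudes = apply(scenario$truth$spec$amplitudes, 1, identity,
                                   simplify = FALSE),
                depth = cfg$depth, bg_rate_per_us = cfg$bg_rate,
                bg_dim = cfg$bg_dim, snr = cfg$snr, seed = cfg$seed)
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, tp))
}

# largest-remainder apportionment of n among the ratio weights
apportion_counts <- function(n, ratio) {
  q <- n * ratio / sum(ratio)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(ratio))
}

#' Configuration of a membrane/protein pseudo-trajectory
#'
#' Pseudo-lipids (one particle each) sit on a leaflet grid in the membrane
#' composition of the study system — cholesterol:POPC:POPE:POPS:SAPI at a
#' 20:14:35:22:9 molar ratio by default — with a small protein chain held
#' well above the leaflet. A contact script moves designated residues to
#' within 3.5 Angstrom of a lipid of a given type in chosen frames (and at
#' least 6 Angstrom from every lipid otherwise), so per-type contact
#' fractions are known exactly by construction.
#'
#' @param n_frames Number of frames.
#' @param n_lipids Lipids in the leaflet; counts per type follow
#'   \code{lipid_ratio} by largest-remainder apportionment.
#' @param lipid_ratio Named molar-ratio weights per residue type.
#' @param contact_script Named list: \code{script[[lipid_type]][[as.character(resid)]]}
#'   is the integer vector of frames (1-based) in which that protein
#'   residue contacts that lipid type.
#' @param spacing Leaflet grid spacing, Angstrom (>= 8 so scripted contacts
#'   never graze a neighbouring lipid).
#' @param jitter Per-frame coordinate jitter standard deviation, Angstrom.
#' @param protein_resids Residue ids of the protein chain (each residue
#'   gets a backbone atom \code{CA} and a sidechain atom \code{SC}).
#' @param seed Integer seed.
#' @return A \code{membrane_config} object.
#' @export
membrane_config <- function(n_frames = 100L, n_lipids = 100L,
                            lipid_ratio = c(CHL1 = 20, POPC = 14, POPE = 35,
                                            POPS = 22, SAPI = 9),
                            contact_script = list(), spacing = 10,
                            jitter = 0.3, protein_resids = c(27L, 29L, 162L, 186L, 225L),
                            seed = 1L) {
  stopifnot(n_frames >= 1L, n_lipids >= length(lipid_ratio), spacing >= 8,
            jitter >= 0, all(lipid_ratio >= 0))
  counts <- apportion_counts(n_lipids, lipid_ratio)
  for (tp in names(contact_script)) {
    if (!tp %in% names(lipid_ratio))
      stop(sprintf("scripted lipid type '%s' not in composition", tp))
    for (rs in names(contact_script[[tp]])) {
      fr <- contact_script[[tp]][[rs]]
      if (any(fr < 1L) || any(fr > n_frames))
        stop("scripted contact frames must lie in [1, n_frames]")
      if (!as.integer(rs) %in% protein_resids)
        stop(sprintf("scripted residue %s is not a protein residue", rs))
    }
  }
  # a residue may touch only one lipid type per frame
  for (rs in as.character(protein_resids)) {
    fr_all <- unlist(lapply(contact_script, function(s) s[[rs]]))
    if (anyDuplicated(fr_all))
      stop(sprintf("residue %s is scripted for two lipid types in the same frame", rs))
  }
  structure(list(n_frames = as.integer(n_frames), lipid_counts = counts,
                 contact_script = contact_script, spacing = spacing,
                 jitter = jitter, protein_resids = as.integer(protein_resids),
                 seed = as.integer(seed)),
            class = "membrane_config")
}

#' Generate a membrane/protein trajectory with scripted contacts
#'
#' @param config A [membrane_config()].
#' @return List with \code{trajectory} (an [md_trajectory()]), \code{truth}
#'   (data frame \code{resid, lipid_type, percent} of constructed contact
#'   percentages for every residue x type pair), and \code{config}.
#' @export
make_membrane_trajectory <- function(config) {
  stopifnot(inherits(config, "membrane_config"))
  counts <- config$lipid_counts
  n_lip <- sum(counts)
  side <- ceiling(sqrt(n_lip))
  if (side * config$spacing > 9999) stop("leaflet grid exceeds PDB coordinate field")
  gx <- ((seq_len(n_lip) - 1L) %% side) * config$spacing
  gy <- ((seq_len(n_lip) - 1L) %/% side) * config$spacing
  types <- rep(names(counts), counts)

  prot_res <- config$protein_resids
  n_prot <- length(prot_res)
  lip_atoms <- data.frame(serial = seq_len(n_lip), name = "C1", resname = types,
                          resid = seq_len(n_lip), chain = "L",
                          stringsAsFactors = FALSE)
  prot_atoms <- data.frame(
    serial = n_lip + seq_len(2L * n_prot),
    name = rep(c("CA", "SC"), n_prot),
    resname = "RES",
    resid = rep(prot_res, each = 2L),
    chain = "P", stringsAsFactors = FALSE)
  atoms <- rbind(lip_atoms, prot_atoms)

  home_x <- seq(0, by = config$spacing, length.out = n_prot)
  nf <- config$n_frames
  coords <- array(0, c(nrow(atoms), 3L, nf))
  set.seed(config$seed)
  for (f in seq_len(nf)) {
    lx <- gx + rnorm(n_lip, 0, config$jitter)
    ly <- gy + rnorm(n_lip, 0, config$jitter)
    lz <- rnorm(n_lip, 0, config$jitter)
    coords[seq_len(n_lip), , f] <- cbind(lx, ly, lz)
    for (p in seq_len(n_prot)) {
      base <- n_lip + 2L * (p - 1L)
      ca <- c(home_x[p] + rnorm(1, 0, config$jitter),
              rnorm(1, 0, config$jitter), 30 + rnorm(1, 0, config$jitter))
      sc <- ca + c(0, 0, 2)
      for (tp in names(config$contact_script)) {
        fr <- config$contact_script[[tp]][[as.character(prot_res[p])]]
        if (!is.null(fr) && f %in% fr) {
          target <- which(types == tp)[1]          # first lipid of that type
          sc <- c(lx[target], ly[target], lz[target] + 3.5)
        }
      }
      coords[base + 1L, , f] <- ca
      coords[base + 2L, , f] <- sc
    }
  }
  traj <- md_trajectory(atoms, coords)

  truth <- do.call(rbind, lapply(prot_res, function(rs) {
    data.frame(resid = rs, lipid_type = names(counts),
               percent = vapply(names(counts), function(tp) {
                 fr <- config$contact_script[[tp]][[as.character(rs)]]
                 if (is.null(fr)) 0 else 100 * length(unique(fr)) / nf
               }, numeric(1)), stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(trajectory = traj, truth = truth, config = config)
}
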