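# MD trajectory statistics: minimum-distance series, salt bridges, lipid
# contact percentages, and RMSD versus the first frame.

#' Construct an MD trajectory object
#'
#' @param atoms Data frame with columns \code{serial, name, resname, resid,
#'   chain} describing the (fixed) atom list.
#' @param coords Numeric array \code{[n_atoms, 3, n_frames]} of coordinates
#'   in Angstrom; identical atom ordering in every frame.
#' @param frame_times Optional per-frame times, ns.
#' @return An \code{md_trajectory} object.
#' @export
md_trajectory <- function(atoms, coords, frame_times = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("serial", "name", "resname", "resid", "chain") %in% names(atoms)))
  coords <- as.array(coords)
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L ||
      dim(coords)[1] != nrow(atoms))
    stop("`coords` must be an [n_atoms, 3, n_frames] array matching `atoms`")
  if (any(!is.finite(coords))) stop("all coordinates must be finite")
  if (!is.null(frame_times)) stopifnot(length(frame_times) == dim(coords)[3])
  structure(list(atoms = atoms, coords = coords, frame_times = frame_times),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("MD trajectory: %d atoms, %d frames, %d residues\n",
              nrow(x$atoms), dim(x$coords)[3],
              length(unique(paste(x$atoms$chain, x$atoms$resid)))))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

# ---- atom selection grammar ------------------------------------------------
# expr  := term ("or" term)*
# term  := factor ("and" factor)*
# factor:= "(" expr ")" | clause
# clause:= ("resid" | "resname" | "name" | "chain") value[,value...]

tokenize_selection <- function(expr) {
  s <- gsub("\\(", " ( ", gsub("\\)", " ) ", expr))
  tok <- strsplit(trimws(s), "\\s+")[[1]]
  tok[nzchar(tok)]
}

parse_selection <- function(tokens, atoms) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }

  parse_clause <- function() {
    key <- take()
    if (!key %in% c("resid", "resname", "name", "chain"))
      stop(sprintf("selection syntax error near '%s'", key))
    val <- take()
    if (is.na(val)) stop(sprintf("selection clause '%s' needs a value", key))
    vals <- strsplit(val, ",")[[1]]
    switch(key,
      resid = atoms$resid %in% as.integer(vals),
      resname = atoms$resname %in% vals,
      name = atoms$name %in% vals,
      chain = atoms$chain %in% vals)
  }
  parse_factor <- function() {
    if (identical(peek(), "(")) {
      take()
      e <- parse_expr()
      if (!identical(take(), ")")) stop("unbalanced parentheses in selection")
      e
    } else parse_clause()
  }
  parse_term <- function() {
    e <- parse_factor()
    while (identical(peek(), "and")) { take(); e <- e & parse_factor() }
    e
  }
  parse_expr <- function() {
    e <- parse_term()
    while (identical(peek(), "or")) { take(); e <- e | parse_term() }
    e
  }
  out <- parse_expr()
  if (pos <= length(tokens))
    stop(sprintf("trailing tokens in selection: '%s'",
                 paste(tokens[pos:length(tokens)], collapse = " ")))
  out
}

#' Select atoms with a small expression grammar
#'
#' Clauses \code{resid N}, \code{resname X}, \code{name A,B} and
#' \code{chain C} (comma lists allowed everywhere) combined with
#' \code{and} / \code{or} and parentheses, e.g.
#' \code{"(resid 225 or resid 162) and name SC"}.
#'
#' @param traj An [md_trajectory()].
#' @param expr Selection string, or an integer vector of atom indices
#'   (returned unchanged after validation).
#' @return Integer vector of atom indices; empty selections are an error
#'   naming the expression.
#' @export
select_atoms <- function(traj, expr) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.numeric(expr)) {
    idx <- as.integer(expr)
    if (length(idx) == 0L || any(idx < 1L) || any(idx > nrow(traj$atoms)))
      stop("numeric selection out of range or empty")
    return(idx)
  }
  mask <- parse_selection(tokenize_selection(expr), traj$atoms)
  idx <- which(mask)
  if (length(idx) == 0L) stop(sprintf("selection matches no atoms: '%s'", expr))
  idx
}

# one frame of a selection as an n x 3 matrix (frame index never drops)
frame_coords <- function(traj, idx, f)
  matrix(traj$coords[idx, , f], ncol = 3L)

# minimum cross distance between coordinate sets A (na x 3) and B (nb x 3);
# per-pair arithmetic matches the exhaustive double loop exactly
min_cross_distance <- function(A, B) {
  best <- Inf
  for (ia in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[ia, 1])^2 + (B[, 2] - A[ia, 2])^2 + (B[, 3] - A[ia, 3])^2
    m <- min(d2)
    if (m < best) best <- m
  }
  sqrt(best)
}

#' Per-frame minimum distance between two selections
#'
#' @param traj An [md_trajectory()].
#' @param sel_a,sel_b Selection expressions or atom index vectors; must be
#'   nonempty and disjoint.
#' @return Numeric vector of per-frame minimum pairwise distances, Angstrom.
#' @export
min_distance_series <- function(traj, sel_a, sel_b) {
  ia <- select_atoms(traj, sel_a)
  ib <- select_atoms(traj, sel_b)
  if (length(intersect(ia, ib)) > 0L) stop("selections must be disjoint")
  vapply(seq_len(n_frames(traj)), function(f)
    min_cross_distance(frame_coords(traj, ia, f), frame_coords(traj, ib, f)),
    numeric(1))
}

#' Salt-bridge contact series
#'
#' Minimum donor-acceptor distance per frame thresholded at the salt-bridge
#' cutoff (4.5 Angstrom by default; a distance equal to the cutoff counts
#' as a contact).
#'
#' @inheritParams min_distance_series
#' @param donor_sel,acceptor_sel Donor and acceptor atom selections.
#' @param cutoff Contact cutoff, Angstrom.
#' @return A \code{contact_series}: list with \code{min_dist} (Angstrom),
#'   logical \code{contact}, \code{fraction} = mean(contact), and
#'   \code{cutoff}.
#' @export
salt_bridge_series <- function(traj, donor_sel, acceptor_sel, cutoff = 4.5) {
  md <- min_distance_series(traj, donor_sel, acceptor_sel)
  contact <- md <= cutoff
  structure(list(min_dist = md, contact = contact, fraction = mean(contact),
                 cutoff = cutoff),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("Contact series: %d frames, cutoff %.2f A, contact fraction %.3f\n",
              length(x$min_dist), x$cutoff, x$fraction))
  invisible(x)
}

#' Lipid contact percentage of simulation time, by lipid type
#'
#' For each lipid residue type, the percentage of frames in which any atom
#' of the residue selection lies within the cutoff (4.0 Angstrom by
#' default, boundary inclusive) of any atom of any lipid of that type.
#'
#' @inheritParams min_distance_series
#' @param residue_sel Selection for the protein residue of interest.
#' @param lipid_resnames Character vector of lipid residue names (e.g.
#'   \code{c("CHL1", "POPC", "POPE", "POPS", "SAPI")}).
#' @param cutoff Contact cutoff, Angstrom.
#' @return Data frame with columns \code{lipid_type} and \code{percent};
#'   unknown residue names warn and report 0.
#' @export
lipid_contact_percentages <- function(traj, residue_sel, lipid_resnames,
                                      cutoff = 4.0) {
  if (length(lipid_resnames) == 0L) stop("`lipid_resnames` must be nonempty")
  ia <- select_atoms(traj, residue_sel)
  pct <- vapply(lipid_resnames, function(rn) {
    ib <- which(traj$atoms$resname == rn)
    if (length(ib) == 0L) {
      warning(sprintf("no atoms with residue name '%s'; reporting 0%%", rn))
      return(0)
    }
    md <- vapply(seq_len(n_frames(traj)), function(f)
      min_cross_distance(frame_coords(traj, ia, f), frame_coords(traj, ib, f)),
      numeric(1))
    100 * mean(md <= cutoff)
  }, numeric(1))
  data.frame(lipid_type = lipid_resnames, percent = unname(pct),
             stringsAsFactors = FALSE)
}

# optimal proper-rotation (Kabsch) superposition of P onto Q, both centered
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)                     # 3x3
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)                   # P %*% R best matches Q
}

#' RMSD series versus the first frame
#'
#' Per frame, the selection is optimally superposed onto frame 1 by
#' least-squares rigid-body alignment (translation plus proper rotation)
#' and the root-mean-square deviation over the selected atoms reported.
#' Coincident selections (all atoms at one point) fall back to
#' translation-only superposition with a warning.
#'
#' @inheritParams min_distance_series
#' @param sel Atom selection.
#' @param superpose If \code{FALSE}, raw coordinates are compared without
#'   alignment.
#' @return Numeric vector of per-frame RMSDs, Angstrom; the first entry is 0.
#' @export
rmsd_series <- function(traj, sel, superpose = TRUE) {
  idx <- select_atoms(traj, sel)
  if (superpose && length(idx) < 2L)
    stop("superposition needs at least 2 atoms")
  ref <- frame_coords(traj, idx, 1L)
  refc <- sweep(ref, 2, colMeans(ref))
  vapply(seq_len(n_frames(traj)), function(f) {
    if (f == 1L) return(0)                 # reference frame by definition
    X <- frame_coords(traj, idx, f)
    if (!superpose) return(sqrt(mean(rowSums((X - ref)^2))))
    Xc <- sweep(X, 2, colMeans(X))
    sv_ok <- svd(crossprod(Xc, refc))$d
    if (all(sv_ok < 1e-10)) {
      warning("coincident selection; translation-only superposition")
      return(sqrt(mean(rowSums((Xc - refc)^2))))
    }
    R <- kabsch_rotation(Xc, refc)
    sqrt(mean(rowSums((Xc %*% R - refc)^2)))
  }, numeric(1))
}
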