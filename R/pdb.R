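# Multi-model PDB reader/writer (fixed-column ATOM/HETATM records framed by
# MODEL/ENDMDL). Residue names are read from columns 18-21 so CHARMM-style
# 4-character lipid names (CHL1, POPC, SAPI, ...) survive a round trip.

parse_atom_line <- function(ln) {
  list(serial = as.integer(substr(ln, 7, 11)),
       name = trimws(substr(ln, 13, 16)),
       resname = trimws(substr(ln, 18, 21)),
       chain = trimws(substr(ln, 22, 22)),
       resid = as.integer(substr(ln, 23, 26)),
       x = as.numeric(substr(ln, 31, 38)),
       y = as.numeric(substr(ln, 39, 46)),
       z = as.numeric(substr(ln, 47, 54)))
}

#' Read a multi-model PDB file as a trajectory
#'
#' Frames are MODEL/ENDMDL blocks in file order (a file without MODEL
#' records yields one frame). The atom list (serial, name, residue) must be
#' identical in every model; mismatches are an error citing the offending
#' model numbers. Coordinates are parsed at PDB precision (0.001 Angstrom).
#'
#' @param path PDB file path.
#' @return An [md_trajectory()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("PDB file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  frames <- list(); model_ids <- integer(0)
  cur <- character(0); cur_id <- NA_integer_; in_model <- FALSE; seen_model <- FALSE
  flush <- function() {
    if (length(cur)) {
      frames[[length(frames) + 1L]] <<- cur
      model_ids[length(model_ids) + 1L] <<- cur_id
    }
    cur <<- character(0)
  }
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      flush(); in_model <- TRUE; seen_model <- TRUE
      cur_id <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      if (is.na(cur_id)) cur_id <- length(frames) + 1L
    } else if (startsWith(r, "ENDMDL")) {
      flush(); in_model <- FALSE
    } else if (r %in% c("ATOM  ", "HETATM")) {
      if (!seen_model) cur_id <- 1L
      cur <- c(cur, lines[i])
    }
  }
  flush()
  if (length(frames) == 0L) stop(sprintf("no ATOM/HETATM records in %s", path))

  parsed <- lapply(frames, function(fl) {
    p <- lapply(fl, parse_atom_line)
    list(atoms = data.frame(serial = vapply(p, `[[`, integer(1), "serial"),
                            name = vapply(p, `[[`, character(1), "name"),
                            resname = vapply(p, `[[`, character(1), "resname"),
                            resid = vapply(p, `[[`, integer(1), "resid"),
                            chain = vapply(p, `[[`, character(1), "chain"),
                            stringsAsFactors = FALSE),
         xyz = cbind(vapply(p, `[[`, numeric(1), "x"),
                     vapply(p, `[[`, numeric(1), "y"),
                     vapply(p, `[[`, numeric(1), "z")))
  })
  a1 <- parsed[[1]]$atoms
  for (f in seq_along(parsed)[-1]) {
    af <- parsed[[f]]$atoms
    if (nrow(af) != nrow(a1))
      stop(sprintf("atom count mismatch between model %d (%d atoms) and model %d (%d atoms)",
                   model_ids[1], nrow(a1), model_ids[f], nrow(af)))
    if (!identical(af[c("name", "resname", "resid", "chain")],
                   a1[c("name", "resname", "resid", "chain")]))
      stop(sprintf("atom ordering differs between model %d and model %d",
                   model_ids[1], model_ids[f]))
  }
  coords <- array(0, c(nrow(a1), 3L, length(parsed)))
  for (f in seq_along(parsed)) coords[, , f] <- parsed[[f]]$xyz
  md_trajectory(a1, coords)
}

pdb_atom_name <- function(nm) {
  # short names start in column 14 per PDB convention
  if (nchar(nm) >= 4L) sprintf("%-4s", substr(nm, 1, 4)) else sprintf(" %-3s", nm)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj An [md_trajectory()].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$atoms
  nf <- n_frames(traj)
  con <- file(path, "w"); on.exit(close(con))
  names4 <- vapply(a$name, pdb_atom_name, character(1))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                       a$serial, names4, a$resname, a$chain, a$resid,
                       traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f], 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
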