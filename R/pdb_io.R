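# Structure and trajectory I/O. Parsing of the fixed-width PDB format is
# delegated to bio3d; this layer maps bio3d's atom table onto the molsys
# data model, applies the water/ion and altloc policies, and validates the
# invariants the rest of the package relies on.

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SPC", "SOL")
ION_RESNAMES   <- c("NA", "CL", "K", "MG", "CA2", "ZN", "SOD", "CLA", "POT")

#' Read a PDB structure
#'
#' Reads ATOM/HETATM records into a [molsys()]. Waters and monatomic ions
#' are dropped by default (they never occlude surface nor contribute
#' interaction energy in this package's analyses); other HETATM residues
#' are kept and labelled with the `cofactor` role. Protein ATOM records
#' get the `receptor` role; use [set_roles()] to override, e.g. to mark
#' peptide-fragment chains as `ligand`. Where a file carries alternate
#' locations, only the highest-occupancy conformer of each atom is kept.
#'
#' Author residue numbering is preserved verbatim; all reports use it.
#'
#' @param path path to a PDB file.
#' @param keep_waters keep water/ion records (role `cofactor`)?
#' @return A `molsys` without nonbonded parameters assigned
#'   (see [assign_parameters()]).
#' @export
read_pdb <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms in '", path, "'")
  bad <- which(is.na(at$x) | is.na(at$y) | is.na(at$z))
  if (length(bad) > 0)
    stop("malformed coordinates at ATOM/HETATM record(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " of '", path, "'")
  at$chain[is.na(at$chain)] <- " "
  # altloc: keep the highest-occupancy conformer per (chain, resseq, name)
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    at$o[is.na(at$o)] <- 1
    key <- paste(at$chain, at$resno, at$elety)
    ord <- order(key, -at$o)
    at <- at[ord, ][!duplicated(key[ord]), ]
    at <- at[order(as.integer(rownames(at))), ]
  }
  solvent <- at$resid %in% c(WATER_RESNAMES, ION_RESNAMES)
  if (!keep_waters) at <- at[!solvent, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms in '", path, "' after water removal")
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- guess_element(at$elety[bad])
  atom <- data.frame(serial = at$eleno, name = at$elety,
                     elem = trimws(elem), chain = at$chain,
                     resseq = at$resno, resname = at$resid,
                     x = at$x, y = at$y, z = at$z,
                     stringsAsFactors = FALSE)
  het <- at$type == "HETATM"
  solv_kept <- at$resid %in% c(WATER_RESNAMES, ION_RESNAMES)
  roles <- list(receptor = which(!het & !solv_kept),
                cofactor = which(het | solv_kept))
  molsys(atom, roles)
}

# element symbol from an atom-name token (leading digits stripped,
# first alphabetic character)
guess_element <- function(name) {
  s <- toupper(gsub("[^A-Za-z]", "", name))
  ifelse(nzchar(s), substr(s, 1, 1), "X")
}

#' Write a system to a PDB file
#'
#' Writes all fields the reader parses (serial, name, residue, chain,
#' author numbering, coordinates, element), so
#' `read_pdb(write_pdb(sys, f))` round-trips losslessly.
#'
#' @param sys a `molsys`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(sys, path) {
  a <- sys$atom
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(sys))),
                   resno = a$resseq, resid = a$resname, chain = a$chain,
                   eleno = a$serial, elety = a$name, elesy = a$elem)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL block must contain the same atoms, in the same order, as
#' `system`. Frame times are assigned from a fixed interval.
#'
#' @param path multi-model PDB file.
#' @param system the `molsys` topology the frames correspond to.
#' @param dt frame interval in ns (default 0.1).
#' @param t0 time of the first frame in ns.
#' @return A `molsys_traj` with one frame per MODEL (a MODEL-free file
#'   yields a single frame).
#' @export
read_multimodel_trajectory <- function(path, system, dt = 0.1, t0 = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_model_blocks(path, n_atoms(system))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  xyzm <- pdb$xyz
  if (is.null(dim(xyzm))) xyzm <- matrix(xyzm, nrow = 1)
  nf <- nrow(xyzm)
  nat <- ncol(xyzm) / 3
  if (nat != n_atoms(system))
    stop("trajectory has ", nat, " atoms but system has ", n_atoms(system))
  xyz <- array(0, dim = c(nat, 3, nf))
  for (f in seq_len(nf))
    xyz[, , f] <- matrix(xyzm[f, ], ncol = 3, byrow = TRUE)
  trajectory(system, xyz, t0 + dt * (seq_len(nf) - 1))
}

# count ATOM/HETATM records per MODEL block; error names the first
# mismatching model
check_model_blocks <- function(path, n_expected) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    n <- sum(is_atom)
    if (n != n_expected)
      stop("file has ", n, " atoms but system has ", n_expected)
    return(invisible(1L))
  }
  block <- findInterval(which(is_atom), model_starts)
  counts <- tabulate(block, nbins = length(model_starts))
  bad <- which(counts != n_expected)
  if (length(bad) > 0)
    stop("model ", bad[1], " has ", counts[bad[1]],
         " atoms, expected ", n_expected)
  invisible(length(model_starts))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `molsys_traj`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_trajectory <- function(traj, path) {
  a <- traj$system$atom
  nf <- n_frames(traj)
  xyzm <- matrix(0, nrow = nf, ncol = 3 * nrow(a))
  for (f in seq_len(nf)) xyzm[f, ] <- as.vector(t(frame_coords(traj, f)))
  bio3d::write.pdb(file = path, xyz = xyzm,
                   resno = a$resseq, resid = a$resname, chain = a$chain,
                   eleno = a$serial, elety = a$name, elesy = a$elem)
  invisible(path)
}
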