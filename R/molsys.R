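#' Molecular system container
#'
#' A `molsys` bundles an ordered atom table with role labels. The atom table
#' has one row per atom with columns `serial`, `name`, `elem`, `chain`,
#' `resseq` (author numbering from the source file), `resname`, coordinates
#' `x`, `y`, `z` (Angstrom) and the nonbonded parameters `radius` (vdW
#' radius, Angstrom), `charge` (elementary charge), `epsilon` (kcal/mol) and
#' `rmin_half` (Angstrom). Parameters are `NA` until [assign_parameters()]
#' has run; they are never silently zero.
#'
#' Roles partition atoms into `receptor`, `ligand` and `cofactor` index
#' sets. An atom belongs to at most one role. The ligand role holds the
#' mobile peptide fragments; the cofactor role holds bound small molecules
#' or auxiliary chains that should occlude surface and contribute contacts
#' but are not scanned for sites.
#'
#' @param atom data.frame with the columns listed above (parameter columns
#'   optional; filled with `NA` if absent).
#' @param roles named list of integer atom indices for `receptor`, `ligand`
#'   and `cofactor` (any subset; missing roles are empty).
#' @return An object of class `molsys`.
#' @export
molsys <- function(atom, roles = list()) {
  need <- c("serial", "name", "elem", "chain", "resseq", "resname",
            "x", "y", "z")
  miss <- setdiff(need, names(atom))
  if (length(miss) > 0)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  for (p in c("radius", "charge", "epsilon", "rmin_half"))
    if (is.null(atom[[p]])) atom[[p]] <- NA_real_
  atom <- as.data.frame(atom, stringsAsFactors = FALSE)
  rownames(atom) <- NULL
  key <- paste(atom$chain, atom$resseq, atom$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resseq, name) atoms: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  all_roles <- c("receptor", "ligand", "cofactor")
  roles <- roles[intersect(names(roles), all_roles)]
  for (r in all_roles) if (is.null(roles[[r]])) roles[[r]] <- integer(0)
  roles <- lapply(roles[all_roles], function(i) sort(unique(as.integer(i))))
  idx <- unlist(roles, use.names = FALSE)
  if (anyDuplicated(idx))
    stop("role sets must be disjoint")
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > nrow(atom)))
    stop("role index out of range")
  structure(list(atom = atom, roles = roles), class = "molsys")
}

#' @export
print.molsys <- function(x, ...) {
  nres <- length(unique(res_keys(x)))
  cat(sprintf("molsys: %d atoms, %d residues, %d chains\n",
              nrow(x$atom), nres, length(unique(x$atom$chain))))
  cat(sprintf("  roles: receptor %d, ligand %d, cofactor %d atoms\n",
              length(x$roles$receptor), length(x$roles$ligand),
              length(x$roles$cofactor)))
  if (anyNA(x$atom$radius))
    cat("  parameters: MISSING for", sum(is.na(x$atom$radius)), "atoms\n")
  invisible(x)
}

n_atoms <- function(sys) nrow(sys$atom)

#' Residue keys
#'
#' Residues are addressed throughout the package by a `"chain:resseq"`
#' string key in author numbering, e.g. `"A:112"`.
#'
#' @param sys a `molsys`.
#' @return Character vector, one key per atom.
#' @export
res_keys <- function(sys) paste0(sys$atom$chain, ":", sys$atom$resseq)

#' @rdname res_keys
#' @param chain,resseq chain identifier(s) and author residue number(s).
#' @export
res_key <- function(chain, resseq) paste0(chain, ":", resseq)

# atom indices for a set of residue keys, preserving atom order
atoms_for_residues <- function(sys, keys) {
  which(res_keys(sys) %in% keys)
}

# unique residues in atom order: data.frame(key, chain, resseq, resname)
residue_table <- function(sys) {
  k <- res_keys(sys)
  first <- !duplicated(k)
  data.frame(key = k[first], chain = sys$atom$chain[first],
             resseq = sys$atom$resseq[first],
             resname = sys$atom$resname[first],
             stringsAsFactors = FALSE)
}

#' Coordinates of a system as an n x 3 matrix
#' @param sys a `molsys`.
#' @return Numeric matrix with one row per atom.
#' @export
coords <- function(sys) {
  cbind(x = sys$atom$x, y = sys$atom$y, z = sys$atom$z)
}

#' Assign role labels by atom selection
#'
#' Selections use a small expression language: `chain:A` selects a chain,
#' `resid:112-122` an author residue-number range (`resid:57` a single
#' residue), and comma-separated terms form a union, e.g.
#' `"chain:B,chain:C"`. A selection may also be given directly as an
#' integer vector of atom indices. Atoms assigned to one role are removed
#' from the others, keeping roles disjoint.
#'
#' @param sys a `molsys`.
#' @param receptor,ligand,cofactor selection strings or index vectors;
#'   `NULL` leaves a role unchanged.
#' @return The modified `molsys`.
#' @export
set_roles <- function(sys, receptor = NULL, ligand = NULL, cofactor = NULL) {
  want <- list(receptor = receptor, ligand = ligand, cofactor = cofactor)
  for (r in names(want)) {
    if (is.null(want[[r]])) next
    idx <- if (is.numeric(want[[r]])) as.integer(want[[r]])
           else select_atoms(sys, want[[r]])
    if (length(idx) == 0)
      stop("selection for role '", r, "' matches no atoms")
    sys$roles[[r]] <- sort(unique(idx))
    for (o in setdiff(names(sys$roles), r))
      sys$roles[[o]] <- setdiff(sys$roles[[o]], idx)
  }
  sys
}

#' Evaluate an atom selection expression
#'
#' @param sys a `molsys`.
#' @param expr selection string, see [set_roles()] for the syntax.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(sys, expr) {
  terms <- strsplit(trimws(expr), ",", fixed = TRUE)[[1]]
  hit <- logical(n_atoms(sys))
  for (t in terms) {
    t <- trimws(t)
    if (grepl("^chain:", t)) {
      hit <- hit | sys$atom$chain == sub("^chain:", "", t)
    } else if (grepl("^resid:", t)) {
      rng <- sub("^resid:", "", t)
      parts <- as.integer(strsplit(rng, "-", fixed = TRUE)[[1]])
      if (anyNA(parts) || length(parts) > 2)
        stop("bad resid term in selection: '", t, "'")
      lo <- parts[1]; hi <- parts[length(parts)]
      hit <- hit | (sys$atom$resseq >= lo & sys$atom$resseq <= hi)
    } else {
      stop("unknown selection term: '", t, "'")
    }
  }
  which(hit)
}

#' Split the ligand role into per-chain fragments
#'
#' Each chain within the ligand role is treated as one independent peptide
#' fragment, mirroring a simulation setup in which every fragment is a
#' separate chain.
#'
#' @param sys a `molsys`.
#' @return Named list of atom index vectors, names are fragment ids
#'   (the chain identifiers).
#' @export
fragment_partition <- function(sys) {
  lig <- sys$roles$ligand
  if (length(lig) == 0) return(list())
  split(lig, sys$atom$chain[lig])
}

#' Trajectory container
#'
#' A fixed-topology sequence of coordinate frames over one [molsys()].
#'
#' @param system a `molsys`.
#' @param xyz numeric array of dimension `n_atoms x 3 x n_frames`.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @return An object of class `molsys_traj`.
#' @export
trajectory <- function(system, xyz, times) {
  if (!inherits(system, "molsys")) stop("system must be a molsys")
  if (length(dim(xyz)) != 3 || dim(xyz)[1] != n_atoms(system) ||
      dim(xyz)[2] != 3)
    stop("xyz must be an n_atoms x 3 x n_frames array")
  nf <- dim(xyz)[3]
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(system = system, xyz = xyz, times = as.numeric(times)),
            class = "molsys_traj")
}

#' @export
print.molsys_traj <- function(x, ...) {
  cat(sprintf("molsys_traj: %d frames x %d atoms, t = %.3g..%.3g ns\n",
              n_frames(x), n_atoms(x$system), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `molsys_traj`.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Coordinates of one frame
#' @param traj a `molsys_traj`.
#' @param i frame index (1-based).
#' @return Numeric `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  m <- traj$xyz[, , i, drop = TRUE]
  dim(m) <- c(dim(traj$xyz)[1], 3)
  colnames(m) <- c("x", "y", "z")
  m
}

# single-frame trajectory from a system's own coordinates
as_trajectory <- function(sys, time = 0) {
  xyz <- array(coords(sys), dim = c(n_atoms(sys), 3, 1))
  trajectory(sys, xyz, time)
}

# mean structure over frames (n x 3)
average_coords <- function(traj) {
  apply(traj$xyz, c(1, 2), mean)
}
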