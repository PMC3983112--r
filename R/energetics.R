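# Pairwise nonbonded interaction energies (Coulomb + Lennard-Jones) with
# a switched cutoff, interaction-energy time series, and salt-bridge
# detection.

#' @keywords internal
COULOMB_K <- 332.0636  # kcal*Angstrom/(mol*e^2)

#' Cubic switching function
#'
#' The standard C1-continuous switching function used with truncated
#' nonbonded interactions: 1 for `r <= switch_on`, 0 for `r >= cutoff`,
#' and `((roff^2 - r^2)^2 (roff^2 + 2 r^2 - 3 ron^2)) / (roff^2 -
#' ron^2)^3` in between.
#'
#' @param r distances (Angstrom).
#' @param switch_on switch-on distance (Angstrom).
#' @param cutoff cutoff distance (Angstrom).
#' @return Switching factors in `[0, 1]`.
#' @export
switching_function <- function(r, switch_on = 10, cutoff = 12) {
  if (switch_on >= cutoff) stop("switch_on must be < cutoff")
  ron2 <- switch_on^2; roff2 <- cutoff^2
  r2 <- r^2
  s <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  s[r <= switch_on] <- 1
  s[r >= cutoff] <- 0
  s
}

#' Nonbonded interaction energy between two atom groups
#'
#' Electrostatic term `332.0636 q_i q_j / (eps_r r_ij) S(r_ij)` and
#' Lennard-Jones term `eps_ij ((rmin_ij/r_ij)^12 - 2 (rmin_ij/r_ij)^6)
#' S(r_ij)` with Lorentz-Berthelot style combination (`eps_ij =
#' sqrt(eps_i eps_j)`, `rmin_ij = rmin_half_i + rmin_half_j`) and the
#' cubic switching function `S` (see [switching_function()]); pairs
#' beyond the cutoff contribute nothing.
#'
#' @param xyz `n x 3` coordinate matrix for the whole system (Angstrom).
#' @param sys the parameterized `molsys` the groups index into.
#' @param group_a,group_b disjoint integer atom index sets.
#' @param cutoff,switch_on truncation distances in Angstrom
#'   (defaults 12 and 10).
#' @param dielectric relative dielectric constant (default 1).
#' @return Named numeric vector `c(elec = , vdw = )` in kcal/mol.
#' @export
pair_energy <- function(xyz, sys, group_a, group_b,
                        cutoff = 12, switch_on = 10, dielectric = 1) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("group_a and group_b overlap")
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty atom group")
  check_parameterized(sys, c(group_a, group_b))
  xa <- xyz[group_a, , drop = FALSE]
  xb <- xyz[group_b, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * xa %*% t(xb)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r == 0)) {
    w <- which(r == 0, arr.ind = TRUE)[1, ]
    a <- sys$atom[group_a[w[1]], ]; b <- sys$atom[group_b[w[2]], ]
    stop(sprintf("zero interatomic distance between %s%d:%s and %s%d:%s",
                 a$resname, a$resseq, a$name, b$resname, b$resseq, b$name))
  }
  within <- r < cutoff
  if (!any(within)) return(c(elec = 0, vdw = 0))
  s <- switching_function(r, switch_on, cutoff)
  at <- sys$atom
  qq <- outer(at$charge[group_a], at$charge[group_b])
  elec <- sum((COULOMB_K / dielectric) * qq[within] *
                s[within] / r[within])
  eps <- sqrt(outer(at$epsilon[group_a], at$epsilon[group_b]))
  rmin <- outer(at$rmin_half[group_a], at$rmin_half[group_b], "+")
  t6 <- (rmin[within] / r[within])^6
  vdw <- sum(eps[within] * (t6^2 - 2 * t6) * s[within])
  c(elec = elec, vdw = vdw)
}

#' Interaction-energy time series between residue sets
#'
#' Per-frame [pair_energy()] over all atoms of two residue sets, with the
#' mean and standard deviation of the total stored as attributes (the
#' convention used when reporting a site's energy as mean +/- sd).
#'
#' @param traj a parameterized `molsys_traj`.
#' @param site_residues,fragment_residues character vectors of
#'   `"chain:resseq"` residue keys (see [res_key()]); must be non-empty
#'   and disjoint.
#' @param cutoff,switch_on,dielectric see [pair_energy()].
#' @param site_id,fragment_id optional identifiers carried as attributes.
#' @return Object of class `energy_series`: data.frame with columns
#'   `frame`, `time_ns`, `elec`, `vdw`, `total` (kcal/mol) and
#'   attributes `mean`, `sd`, `cutoff`, `switch_on`.
#' @export
energy_series <- function(traj, site_residues, fragment_residues,
                          cutoff = 12, switch_on = 10, dielectric = 1,
                          site_id = NA, fragment_id = NA) {
  if (length(site_residues) == 0 || length(fragment_residues) == 0)
    stop("empty residue set")
  sys <- traj$system
  ga <- atoms_for_residues(sys, site_residues)
  gb <- atoms_for_residues(sys, fragment_residues)
  if (length(ga) == 0)
    stop("site residues not found: ",
         paste(site_residues, collapse = ", "))
  if (length(gb) == 0)
    stop("fragment residues not found: ",
         paste(fragment_residues, collapse = ", "))
  nf <- n_frames(traj)
  e <- matrix(0, nf, 2)
  for (f in seq_len(nf))
    e[f, ] <- pair_energy(frame_coords(traj, f), sys, ga, gb,
                          cutoff, switch_on, dielectric)
  out <- data.frame(frame = seq_len(nf), time_ns = traj$times,
                    elec = e[, 1], vdw = e[, 2], total = e[, 1] + e[, 2])
  structure(out, class = c("energy_series", "data.frame"),
            mean = mean(out$total), sd = stats::sd(out$total),
            cutoff = cutoff, switch_on = switch_on,
            site_id = site_id, fragment_id = fragment_id)
}

# charged side-chain group atoms for salt-bridge detection
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS  <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))
HIS_ATOMS    <- list(HIS = c("ND1", "NE2"))

charged_atom_idx <- function(sys, table) {
  hits <- integer(0)
  for (rn in names(table))
    hits <- c(hits, which(sys$atom$resname == rn &
                            sys$atom$name %in% table[[rn]]))
  # C-terminal carboxylate oxygens count as acidic
  sort(hits)
}

#' Detect salt bridges across a trajectory
#'
#' A salt bridge is a contact between a side-chain carboxylate oxygen
#' (Asp OD1/OD2, Glu OE1/OE2, or a C-terminal OXT) and a side-chain
#' nitrogen of a basic residue (Lys NZ, Arg NH1/NH2/NE, optionally His
#' ND1/NE2) at or below the distance cutoff. One event is reported per
#' (acidic atom, basic atom) pair that is formed in at least one frame,
#' with a per-frame formed flag and the occupancy fraction.
#'
#' @param traj a `molsys_traj`.
#' @param cutoff distance cutoff in Angstrom (default 3.2); a pair at
#'   3.21 Angstrom is not counted.
#' @param min_occupancy drop events formed in less than this fraction of
#'   frames.
#' @param include_his count histidine ND1/NE2 as basic (off by default:
#'   neutral His is the common state at physiological pH).
#' @param group_a,group_b optional atom index sets; when given, only
#'   pairs with one atom in each set are considered (e.g. site vs
#'   fragment).
#' @return Object of class `salt_bridges`: data.frame with one row per
#'   event (acidic and basic atom identity plus `occupancy`), with the
#'   per-frame formed flags in the `"formed"` attribute (events x
#'   frames logical matrix). Zero rows when nothing is found.
#' @export
detect_salt_bridges <- function(traj, cutoff = 3.2, min_occupancy = 0,
                                include_his = FALSE,
                                group_a = NULL, group_b = NULL) {
  sys <- traj$system
  acid <- charged_atom_idx(sys, ACIDIC_ATOMS)
  acid <- sort(unique(c(acid, which(sys$atom$name %in% c("OXT", "OT2")))))
  base_tab <- BASIC_ATOMS
  if (include_his) base_tab <- c(base_tab, HIS_ATOMS)
  base <- charged_atom_idx(sys, base_tab)
  if (!is.null(group_a) && !is.null(group_b)) {
    pairs_dir1 <- expand.grid(a = acid[acid %in% group_a],
                              b = base[base %in% group_b])
    pairs_dir2 <- expand.grid(a = acid[acid %in% group_b],
                              b = base[base %in% group_a])
    pairs <- rbind(pairs_dir1, pairs_dir2)
  } else {
    pairs <- expand.grid(a = acid, b = base)
  }
  if (nrow(pairs) > 0) {
    same_res <- res_keys(sys)[pairs$a] == res_keys(sys)[pairs$b]
    pairs <- pairs[!same_res, , drop = FALSE]
  }
  empty <- structure(
    data.frame(acidic_chain = character(0), acidic_resseq = integer(0),
               acidic_resname = character(0), acidic_name = character(0),
               basic_chain = character(0), basic_resseq = integer(0),
               basic_resname = character(0), basic_name = character(0),
               occupancy = numeric(0), stringsAsFactors = FALSE),
    class = c("salt_bridges", "data.frame"),
    formed = matrix(FALSE, 0, n_frames(traj)), cutoff = cutoff)
  if (nrow(pairs) == 0) return(empty)
  nf <- n_frames(traj)
  formed <- matrix(FALSE, nrow(pairs), nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    d <- sqrt(rowSums((xyz[pairs$a, , drop = FALSE] -
                         xyz[pairs$b, , drop = FALSE])^2))
    formed[, f] <- d <= cutoff
  }
  occ <- rowMeans(formed)
  keep <- occ > 0 & occ >= min_occupancy
  if (!any(keep)) return(empty)
  pairs <- pairs[keep, , drop = FALSE]
  at <- sys$atom
  out <- data.frame(
    acidic_chain = at$chain[pairs$a], acidic_resseq = at$resseq[pairs$a],
    acidic_resname = at$resname[pairs$a], acidic_name = at$name[pairs$a],
    basic_chain = at$chain[pairs$b], basic_resseq = at$resseq[pairs$b],
    basic_resname = at$resname[pairs$b], basic_name = at$name[pairs$b],
    occupancy = occ[keep], stringsAsFactors = FALSE)
  structure(out, class = c("salt_bridges", "data.frame"),
            formed = formed[keep, , drop = FALSE], cutoff = cutoff)
}

#' Write an energy series as TSV
#'
#' Columns: `frame  time_ns  elec  vdw  total`.
#'
#' @param x an `energy_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_energy_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
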