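# Sphere-point (Shrake-Rupley style) solvent-accessible surface areas and
# the RASAS occupancy measure built on them.
#
# Points are a deterministic generalized-spiral (Fibonacci) set, so every
# result is reproducible without a random seed and the discretization
# error of an isolated sphere is testable.

#' Deterministic Fibonacci sphere-point set
#'
#' Near-uniform points on the unit sphere from the golden-angle spiral.
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Point-occlusion tolerance: a sample point exactly on an occluder's
# probe-expanded surface (within TOL_EQ Angstrom) is treated as occluded
# only when the occluder precedes the target atom in atom order. This
# tie-break makes exactly coincident duplicate atoms contribute one
# sphere's worth of area in total instead of zero or two.
TOL_EQ <- 1e-9

#' Solvent-accessible surface area by sphere-point sampling
#'
#' For each target atom, `n_points` points are placed on its
#' probe-expanded sphere of radius `r + probe`; a point is occluded when
#' it lies inside any other atom's probe-expanded sphere (atoms from
#' `target` and `context` both occlude). The per-atom area is
#' `accessible fraction x 4 pi (r + probe)^2`. Deterministic for a fixed
#' point count.
#'
#' @param xyz `n x 3` coordinate matrix (Angstrom).
#' @param radii per-atom vdW radii (Angstrom), length `nrow(xyz)`.
#' @param target integer indices of atoms whose area is computed.
#' @param context integer indices of additional occluding atoms.
#' @param probe probe radius in Angstrom (default 1.4, a water-sized
#'   probe).
#' @param n_points sphere points per atom (>= 100; default 960).
#' @return Numeric vector of per-atom areas (Angstrom^2), one per target
#'   atom.
#' @export
sasa_atoms <- function(xyz, radii, target, context = integer(0),
                       probe = 1.4, n_points = 960) {
  if (n_points < 100)
    stop("n_points must be >= 100 for acceptable accuracy")
  occl <- sort(unique(c(target, context)))
  if (anyNA(radii[occl]))
    stop("unparameterized atom (missing vdW radius) in target/context")
  if (any(radii[occl] <= 0))
    stop("non-positive vdW radius in target/context")
  pts0 <- fibonacci_sphere(n_points)
  R <- radii + probe                      # probe-expanded radii
  oc_xyz <- xyz[occl, , drop = FALSE]
  oc_R2 <- R[occl]^2
  oc_norm2 <- rowSums(oc_xyz^2)
  areas <- numeric(length(target))
  for (k in seq_along(target)) {
    i <- target[k]
    Ri <- R[i]
    # prescreen occluders: spheres must intersect the point shell
    d_ctr <- sqrt(colSums((t(oc_xyz) - xyz[i, ])^2))
    nb <- which(occl != i & d_ctr < Ri + R[occl])
    if (length(nb) == 0) {
      areas[k] <- 4 * pi * Ri^2
      next
    }
    pts <- pts0 * Ri
    pts[, 1] <- pts[, 1] + xyz[i, 1]
    pts[, 2] <- pts[, 2] + xyz[i, 2]
    pts[, 3] <- pts[, 3] + xyz[i, 3]
    d2 <- outer(rowSums(pts^2), rep(1, length(nb))) -
      2 * pts %*% t(oc_xyz[nb, , drop = FALSE])
    d2 <- sweep(d2, 2, oc_norm2[nb], "+")
    lim <- oc_R2[nb]
    strict <- sweep(d2, 2, lim - TOL_EQ, "<")
    on_surface <- abs(sweep(d2, 2, lim, "-")) <= TOL_EQ
    precedes <- occl[nb] < i
    blocked <- strict | sweep(on_surface, 2, precedes, "&")
    acc <- rowSums(blocked) == 0
    areas[k] <- mean(acc) * 4 * pi * Ri^2
  }
  areas
}

# per-frame total site SASA for a trajectory
frame_sasa_total <- function(traj, target, context, probe, n_points) {
  radii <- traj$system$atom$radius
  vapply(seq_len(n_frames(traj)), function(f)
    sum(sasa_atoms(frame_coords(traj, f), radii, target, context,
                   probe, n_points)),
    numeric(1))
}

# Backbone atom names excluded in side-chain-only mode (heavy backbone
# plus common backbone hydrogens and terminal oxygens).
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2",
                    "H", "HN", "HA", "HA1", "HA2", "HA3",
                    "H1", "H2", "H3")

# side-chain atom indices for a residue-key set; glycine (or any residue
# whose side chain is absent) contributes its CA as a pseudo-side-chain
sidechain_atoms <- function(sys, keys) {
  idx <- atoms_for_residues(sys, keys)
  k <- res_keys(sys)[idx]
  sc <- idx[!(sys$atom$name[idx] %in% BACKBONE_NAMES)]
  have <- unique(k[!(sys$atom$name[idx] %in% BACKBONE_NAMES)])
  bare <- setdiff(unique(k), have)
  if (length(bare) > 0) {
    ca <- idx[sys$atom$name[idx] == "CA" & k %in% bare]
    sc <- sort(c(sc, ca))
    still <- setdiff(bare, res_keys(sys)[ca])
    if (length(still) > 0)
      stop("residues with no side-chain atoms (and no CA): ",
           paste(still, collapse = ", "))
  }
  sc
}

#' RASAS series: ratio of available solvent-accessible surface
#'
#' RASAS for a binding site is the ratio of the site's SASA computed with
#' the ligand present (numerator) to its SASA with the ligand atoms
#' ignored (denominator), recomputed frame by frame. It reports the
#' portion of the site not occupied by the ligand: 1 means no binding,
#' lower values mean higher occupancy. Because receptor and cofactor
#' atoms occlude identically in numerator and denominator, conformational
#' SASA changes cancel and only ligand occlusion moves the ratio. With a
#' 1.4 Angstrom probe the ratio drops below 1 exactly when a ligand
#' atom's vdW surface comes within 2.8 Angstrom (twice the probe radius)
#' of a site atom's vdW surface.
#'
#' By default only side-chain atoms form the target (glycine contributes
#' its CA), so backbone surface does not dilute the signal; backbone
#' atoms still occlude as context.
#'
#' @param traj a parameterized `molsys_traj`.
#' @param site a [site_definition()] or character vector of
#'   `"chain:resseq"` residue keys.
#' @param ligand_role role label whose atoms count as ligand (default
#'   `"ligand"`); the role may be empty, in which case the ratio is
#'   exactly 1.
#' @param probe probe radius, Angstrom.
#' @param sidechain_only restrict the target to side-chain atoms?
#' @param n_points sphere points per atom.
#' @return Object of class `rasas_series`: data.frame with columns
#'   `frame`, `time_ns`, `numerator_A2`, `denominator_A2`, `rasas`, and
#'   attributes `site_id`, `probe`, `sidechain_only`, `mean`, `sd`.
#' @export
rasas_series <- function(traj, site, ligand_role = "ligand",
                         probe = 1.4, sidechain_only = TRUE,
                         n_points = 960) {
  sys <- traj$system
  keys <- if (inherits(site, "site_def")) site_res_keys(site)
          else as.character(site)
  site_id <- if (inherits(site, "site_def")) site$site_id else NA_integer_
  target <- if (sidechain_only) sidechain_atoms(sys, keys)
            else atoms_for_residues(sys, keys)
  if (length(target) == 0)
    stop("site residues not found in system: ", paste(keys, collapse = ", "))
  check_parameterized(sys)
  lig <- sys$roles[[ligand_role]]
  all_idx <- seq_len(n_atoms(sys))
  ctx_num <- setdiff(all_idx, target)
  ctx_den <- setdiff(ctx_num, lig)
  num <- frame_sasa_total(traj, target, ctx_num, probe, n_points)
  den <- frame_sasa_total(traj, target, ctx_den, probe, n_points)
  ratio <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(frame = seq_len(n_frames(traj)), time_ns = traj$times,
                    numerator_A2 = num, denominator_A2 = den,
                    rasas = ratio)
  structure(out, class = c("rasas_series", "data.frame"),
            site_id = site_id, probe = probe,
            sidechain_only = sidechain_only,
            mean = mean(ratio, na.rm = TRUE),
            sd = stats::sd(ratio, na.rm = TRUE))
}

#' Whole-surface coverage series (1 - RASAS of the receptor)
#'
#' The fraction of the receptor's solvent-accessible surface occluded by
#' ligand fragments, frame by frame: `1 - SASA(with ligand) /
#' SASA(ligand ignored)` with the entire receptor as the target. The
#' default 2.5 Angstrom probe makes a drop in accessibility correspond to
#' a ligand within a 5 Angstrom proximity of the surface.
#'
#' @param traj a parameterized `molsys_traj`.
#' @param probe probe radius, Angstrom (default 2.5).
#' @param ligand_role role label for the ligand atoms.
#' @param n_points sphere points per atom.
#' @return Object of class `coverage_series`: data.frame with columns
#'   `frame`, `time_ns`, `coverage` (in `[0, 1]`).
#' @export
surface_coverage <- function(traj, probe = 2.5, ligand_role = "ligand",
                             n_points = 960) {
  sys <- traj$system
  target <- sys$roles$receptor
  if (length(target) == 0) stop("receptor role is empty")
  check_parameterized(sys)
  lig <- sys$roles[[ligand_role]]
  ctx_num <- setdiff(seq_len(n_atoms(sys)), target)
  ctx_den <- setdiff(ctx_num, lig)
  num <- frame_sasa_total(traj, target, ctx_num, probe, n_points)
  den <- frame_sasa_total(traj, target, ctx_den, probe, n_points)
  cov <- ifelse(den > 0, 1 - num / den, NA_real_)
  out <- data.frame(frame = seq_len(n_frames(traj)), time_ns = traj$times,
                    coverage = cov)
  structure(out, class = c("coverage_series", "data.frame"), probe = probe,
            mean = mean(cov, na.rm = TRUE))
}

#' Write a RASAS series as TSV
#'
#' Columns: `frame  time_ns  numerator_A2  denominator_A2  rasas`.
#'
#' @param x a `rasas_series`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rasas_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
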