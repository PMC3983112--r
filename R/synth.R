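# Synthetic receptor/fragment systems and trajectories with known
# ground-truth binding events. Motion is kinematic (scripted), not
# physical: the point is exact ground truth for testing the analysis
# stages, not realism.

# run expr with a private, seeded RNG stream, restoring global state
with_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# coarse residue template: backbone (N, CA, C, O) plus a compact 1-2
# atom side chain whose terminal atoms carry any formal charge (compact
# so that residue centroids of contacting partners sit within the 7 A
# pairing distance, as they do for real side chains). `flip` alternates
# the out-of-plane backbone offsets so consecutive residues cannot
# clash.
residue_atoms <- function(resname, ca, t_hat, r_hat, z_hat, flip) {
  b <- if (flip) -1 else 1
  at <- rbind(N = ca - 1.3 * t_hat + 1.8 * b * z_hat,
              CA = ca,
              C = ca + 1.3 * t_hat + 1.8 * b * z_hat,
              O = ca + 1.3 * t_hat + 4.0 * b * z_hat)
  term <- switch(resname,
    GLU = rbind(OE1 = ca + 2.2 * r_hat + 1.1 * z_hat,
                OE2 = ca + 2.2 * r_hat - 1.1 * z_hat),
    LYS = rbind(NZ = ca + 2.2 * r_hat),
    SER = rbind(OG = ca + 2.2 * r_hat),
    ALA = rbind(CB = ca + 2.2 * r_hat),
    rbind(CB = ca + 2.2 * r_hat))
  rbind(at, term)
}

build_chain <- function(resnames, ca_pos, t_hats, r_hats, z_hat, chain,
                        serial0 = 0) {
  rows <- list()
  for (i in seq_along(resnames)) {
    a <- residue_atoms(resnames[i], ca_pos[i, ], t_hats[i, ], r_hats[i, ],
                       z_hat, flip = (i %% 2 == 0))
    rows[[i]] <- data.frame(name = rownames(a), elem = substr(rownames(a), 1, 1),
                            chain = chain, resseq = i,
                            resname = resnames[i],
                            x = a[, 1], y = a[, 2], z = a[, 3],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$serial <- serial0 + seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("serial", "name", "elem", "chain", "resseq", "resname",
          "x", "y", "z")]
}

#' Build a rigid toy receptor
#'
#' A coarse all-atom chain (4 backbone atoms plus a 1--3 atom side
#' chain per residue) laid out on a smooth planar arc, with side chains
#' pointing outward so designated surface patches are solvent-exposed.
#' Patch residues are built as glutamate (net charge -1, on the two
#' carboxylate oxygens) or lysine (net +1, on NZ); all other residues
#' are neutral serine or alanine. This mimics receptors whose peptide
#' binding sites are composed mainly of charged and polar surface
#' residues. Coordinates carry a small seeded jitter (sigma 0.03
#' Angstrom, truncated at 3 sigma) so distinct seeds give distinct but
#' clash-free geometries; the same seed reproduces coordinates exactly.
#'
#' @param n_residues number of residues (>= 10).
#' @param charged_patch_specs list of patch specs, each
#'   `list(residues = <integer vector>, charge = -1 or +1)`; patches
#'   must not overlap.
#' @param seed integer RNG seed.
#' @return A parameterized `molsys` (chain `"A"`, all atoms in the
#'   receptor role).
#' @export
make_toy_receptor <- function(n_residues, charged_patch_specs = list(),
                              seed = 1) {
  if (n_residues < 10) stop("n_residues must be >= 10")
  patch_res <- unlist(lapply(charged_patch_specs, `[[`, "residues"))
  if (anyDuplicated(patch_res))
    stop("overlapping patch specs")
  if (length(patch_res) > 0 &&
      (min(patch_res) < 1 || max(patch_res) > n_residues))
    stop("patch residues out of range")
  resnames <- with_rng(seed,
    sample(c("SER", "ALA"), n_residues, replace = TRUE))
  for (p in charged_patch_specs) {
    if (!p$charge %in% c(-1, 1))
      stop("patch charge must be -1 or +1 (per residue)")
    resnames[p$residues] <- if (p$charge < 0) "GLU" else "LYS"
  }
  spacing <- 3.8
  arc_r <- n_residues * spacing / (2 * pi) * 1.15
  theta <- (seq_len(n_residues) - 1) * spacing / arc_r
  r_hats <- cbind(cos(theta), sin(theta), 0)
  t_hats <- cbind(-sin(theta), cos(theta), 0)
  ca <- arc_r * r_hats
  atom <- build_chain(resnames, ca, t_hats, r_hats, c(0, 0, 1), "A")
  jit <- with_rng(seed + 1, {
    j <- stats::rnorm(3 * nrow(atom), sd = 0.03)
    matrix(pmin(pmax(j, -0.09), 0.09), ncol = 3)
  })
  atom$x <- atom$x + jit[, 1]
  atom$y <- atom$y + jit[, 2]
  atom$z <- atom$z + jit[, 3]
  sys <- molsys(atom, roles = list(receptor = seq_len(nrow(atom))))
  sys <- assign_parameters(sys, quiet = TRUE)
  attr(sys, "arc_radius") <- arc_r
  sys
}

#' Event schedule for a synthetic binding trajectory
#'
#' Each event scripts one fragment's approach / dwell / retreat onto a
#' receptor patch: the fragment leaves its rest position at
#' `approach`, reaches a staging distance just before the dwell, sits
#' at the requested vdW surface-to-surface `gap` over frames
#' `dwell[1]..dwell[2]`, and is back at rest by `retreat`. Binding
#' events use `gap < 2.8` (inside the 1.4 Angstrom probe's detection
#' proximity); negative controls use `gap > 5`.
#'
#' @param fragment index of the fragment the event moves.
#' @param site_residues receptor residue numbers of the target patch.
#' @param approach,retreat first and last frame of the event envelope.
#' @param dwell length-2 vector, first and last dwell frame.
#' @param gap minimum vdW surface-to-surface gap during dwell
#'   (Angstrom; default 0, a van der Waals contact as formed by a salt
#'   bridge).
#' @return A `binding_event` list.
#' @export
binding_event <- function(fragment, site_residues, approach, dwell,
                          retreat, gap = 0) {
  if (length(dwell) != 2 || dwell[1] > dwell[2])
    stop("dwell must be c(first, last)")
  if (!(approach <= dwell[1] && dwell[2] <= retreat))
    stop("need approach <= dwell[1] <= dwell[2] <= retreat")
  if (gap >= 2.8 && gap <= 5)
    stop("gap must be < 2.8 (binding) or > 5 (negative control)")
  structure(list(fragment = fragment, site_residues = site_residues,
                 approach = approach, dwell = dwell, retreat = retreat,
                 gap = gap), class = "binding_event")
}

#' Generate a synthetic trajectory with planted binding events
#'
#' Combines a rigid toy receptor with rigid peptide fragments (one
#' ligand chain each) and moves the fragments kinematically according to
#' an event schedule, plus seeded isotropic Gaussian positional noise on
#' the fragment atoms. Outside their events fragments rest at least 15
#' Angstrom away from the receptor; during a dwell the scripted minimum
#' vdW surface gap to the target patch equals the event's `gap`, so with
#' zero noise the dwell frames are exactly the frames in which the site's
#' RASAS (1.4 Angstrom probe) sits below 1.
#'
#' @param receptor a `molsys` from [make_toy_receptor()].
#' @param fragments list of fragment specs, each
#'   `list(n_residues = , charge = -1/0/+1)`; charged fragments are
#'   poly-Lys or poly-Glu, neutral ones poly-Ser.
#' @param schedule list of [binding_event()]s (may be empty); events of
#'   one fragment must not overlap in time.
#' @param n_frames number of frames.
#' @param dt frame interval, ns.
#' @param noise_sd per-atom Gaussian noise, Angstrom (default 0.2;
#'   0 gives exact scripted geometry).
#' @param seed integer RNG seed; identical seeds reproduce the
#'   trajectory bitwise.
#' @return List with `traj` (a parameterized `molsys_traj`) and `truth`
#'   (data.frame: `event`, `fragment_id`, `dwell_start`, `dwell_end`,
#'   `gap`, `site_residues` comma-joined receptor residue numbers).
#' @export
make_binding_trajectory <- function(receptor, fragments, schedule,
                                    n_frames, dt = 0.1, noise_sd = 0.2,
                                    seed = 1) {
  for (ev in schedule) {
    if (ev$retreat > n_frames || ev$approach < 1)
      stop("schedule extends beyond n_frames")
    if (ev$fragment < 1 || ev$fragment > length(fragments))
      stop("event references unknown fragment ", ev$fragment)
    if (!all(ev$site_residues %in% receptor$atom$resseq))
      stop("event references unknown receptor residues")
  }
  by_frag <- split(schedule, vapply(schedule, `[[`, 0, "fragment"))
  for (evs in by_frag) {
    if (length(evs) < 2) next
    iv <- t(vapply(evs, function(e) c(e$approach, e$retreat), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("events for one fragment overlap in time")
  }
  arc_r <- attr(receptor, "arc_radius")
  if (is.null(arc_r)) arc_r <- max(sqrt(receptor$atom$x^2 +
                                          receptor$atom$y^2))
  # build fragment templates (straight chains in local coordinates)
  rec_n <- nrow(receptor$atom)
  frag_sys <- list()
  serial0 <- rec_n
  for (k in seq_along(fragments)) {
    fs <- fragments[[k]]
    rn <- if (is.null(fs$charge) || fs$charge == 0) "SER"
          else if (fs$charge > 0) "LYS" else "GLU"
    nr <- fs$n_residues
    ca <- cbind((seq_len(nr) - 1) * 3.8, 0, 0)
    tpl <- build_chain(rep(rn, nr), ca, matrix(rep(c(1, 0, 0), nr),
                                               ncol = 3, byrow = TRUE),
                       matrix(rep(c(0, 1, 0), nr), ncol = 3, byrow = TRUE),
                       c(0, 0, 1), chain = LETTERS[k + 1],
                       serial0 = serial0)
    serial0 <- serial0 + nrow(tpl)
    frag_sys[[k]] <- tpl
  }
  atom <- rbind(receptor$atom[, c("serial", "name", "elem", "chain",
                                  "resseq", "resname", "x", "y", "z")],
                do.call(rbind, frag_sys))
  lig_idx <- if (nrow(atom) > rec_n) seq(rec_n + 1, nrow(atom))
             else integer(0)
  sys <- molsys(atom, roles = list(receptor = seq_len(rec_n),
                                   ligand = lig_idx))
  sys <- assign_parameters(sys, quiet = TRUE)
  frag_idx <- lapply(frag_sys, function(t) match(t$serial, sys$atom$serial))
  radii <- sys$atom$radius
  rec_xyz <- coords(receptor)

  # orientation per fragment: side chains face the first event's patch
  # (or the -x direction for event-less fragments); one rigid pose per
  # fragment so interpolated translations keep it rigid
  patch_axis <- function(resseqs) {
    i <- which(receptor$atom$resseq %in% resseqs)
    u <- colMeans(rec_xyz[i, , drop = FALSE])
    u[3] <- 0
    u / sqrt(sum(u^2))
  }
  placed_template <- function(k, u_hat) {
    tpl <- as.matrix(frag_sys[[k]][, c("x", "y", "z")])
    t_hat <- c(-u_hat[2], u_hat[1], 0)
    Rm <- cbind(t_hat, -u_hat, c(0, 0, 1))   # x->tangent, y->-outward
    ctr <- colMeans(tpl)
    sweep(tpl, 2, ctr) %*% t(Rm)
  }
  # fragment atom positions with centroid at `offset` along u_hat from
  # the patch-centroid anchor
  place_at <- function(tpl0, anchor, u_hat, offset) {
    sweep(tpl0, 2, anchor + offset * u_hat, "+")
  }
  min_gap <- function(fxyz, k, site_atoms) {
    fi <- frag_idx[[k]]
    d2 <- outer(rowSums(fxyz^2), rep(1, length(site_atoms))) +
      outer(rep(1, nrow(fxyz)),
            rowSums(rec_xyz[site_atoms, , drop = FALSE]^2)) -
      2 * fxyz %*% t(rec_xyz[site_atoms, , drop = FALSE])
    d <- sqrt(pmax(d2, 0))
    gaps <- d - outer(radii[fi], radii[site_atoms], "+")
    min(gaps)
  }
  offset_for_gap <- function(tpl0, anchor, u_hat, k, site_atoms, gap) {
    f <- function(o) min_gap(place_at(tpl0, anchor, u_hat, o), k,
                             site_atoms) - gap
    stats::uniroot(f, c(0.5, arc_r + 120), tol = 1e-6)$root
  }

  first_event <- lapply(seq_along(fragments), function(k) {
    evs <- Filter(function(e) e$fragment == k, schedule)
    if (length(evs) == 0) NULL else evs[[which.min(
      vapply(evs, `[[`, 0, "approach"))]]
  })
  u0 <- lapply(seq_along(fragments), function(k) {
    if (is.null(first_event[[k]])) {
      ang <- 2 * pi * (k - 0.5) / length(fragments)
      c(cos(ang), sin(ang), 0)
    } else patch_axis(first_event[[k]]$site_residues)
  })
  tpl0 <- lapply(seq_along(fragments), function(k)
    placed_template(k, u0[[k]]))

  rest_gap <- 25
  rest_pos <- lapply(seq_along(fragments), function(k) {
    u <- u0[[k]]
    anchor <- if (is.null(first_event[[k]])) u * arc_r
              else {
                i <- which(receptor$atom$resseq %in%
                             first_event[[k]]$site_residues)
                colMeans(rec_xyz[i, , drop = FALSE])
              }
    o <- offset_for_gap(tpl0[[k]], anchor, u, k,
                        seq_len(rec_n), rest_gap)
    place_at(tpl0[[k]], anchor, u, o)
  })

  nat <- n_atoms(sys)
  xyz <- array(0, dim = c(nat, 3, n_frames))
  for (f in seq_len(n_frames)) xyz[seq_len(rec_n), , f] <- rec_xyz
  for (k in seq_along(fragments))
    for (f in seq_len(n_frames)) xyz[frag_idx[[k]], , f] <- rest_pos[[k]]

  staging_gap <- 6
  truth <- list()
  for (e in seq_along(schedule)) {
    ev <- schedule[[e]]
    k <- ev$fragment
    u <- patch_axis(ev$site_residues)
    site_atoms <- which(receptor$atom$resseq %in% ev$site_residues)
    anchor <- colMeans(rec_xyz[site_atoms, , drop = FALSE])
    o_dwell <- offset_for_gap(tpl0[[k]], anchor, u, k, site_atoms, ev$gap)
    o_stage <- offset_for_gap(tpl0[[k]], anchor, u, k, site_atoms,
                              staging_gap)
    dwell_xyz <- place_at(tpl0[[k]], anchor, u, o_dwell)
    stage_xyz <- place_at(tpl0[[k]], anchor, u, o_stage)
    lerp <- function(a, b, w) a + w * (b - a)
    # approach: rest -> staging over [approach, dwell_start - 1]
    if (ev$dwell[1] > ev$approach) {
      ff <- seq(ev$approach, ev$dwell[1] - 1)
      for (j in seq_along(ff)) {
        w <- j / length(ff)
        xyz[frag_idx[[k]], , ff[j]] <- lerp(rest_pos[[k]], stage_xyz, w)
      }
    }
    for (f in seq(ev$dwell[1], ev$dwell[2]))
      xyz[frag_idx[[k]], , f] <- dwell_xyz
    if (ev$retreat > ev$dwell[2]) {
      ff <- seq(ev$dwell[2] + 1, ev$retreat)
      for (j in seq_along(ff)) {
        w <- j / length(ff)
        xyz[frag_idx[[k]], , ff[j]] <- lerp(stage_xyz, rest_pos[[k]], w)
      }
    }
    truth[[e]] <- data.frame(
      event = e, fragment_id = LETTERS[k + 1],
      dwell_start = ev$dwell[1], dwell_end = ev$dwell[2], gap = ev$gap,
      site_residues = paste(sort(ev$site_residues), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (noise_sd > 0) {
    lig <- sys$roles$ligand
    noise <- with_rng(seed,
      array(stats::rnorm(length(lig) * 3 * n_frames, sd = noise_sd),
            dim = c(length(lig), 3, n_frames)))
    xyz[lig, , ] <- xyz[lig, , ] + noise
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth)
           else data.frame(event = integer(0), fragment_id = character(0),
                           dwell_start = integer(0), dwell_end = integer(0),
                           gap = numeric(0), site_residues = character(0))
  list(traj = trajectory(sys, xyz, dt * (seq_len(n_frames) - 1)),
       truth = truth)
}
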