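# The multi-step binding-site determination pipeline: centroid contact
# pairing at 7 Angstrom, screening at 3 kcal/mol per paired receptor
# residue, splitting of fragments engaging in several independent
# interactions, transitive merging of spatially adjacent candidates, and
# re-scoring of the merged sites with per-residue pruning.

#' Pair receptor residues with fragments by centroid distance
#'
#' A receptor residue is paired with a fragment in a frame when its
#' centroid (unweighted mean of its atom coordinates) lies within
#' `cutoff` of the centroid of any residue of that fragment. The 7
#' Angstrom default is a deliberately permissive first net: candidate
#' regions are thinned afterwards by the energy screen.
#'
#' @param traj a `molsys_traj`.
#' @param fragments named list of ligand atom index sets, one per
#'   fragment (default: ligand role split by chain, see
#'   [fragment_partition()]).
#' @param cutoff centroid-centroid distance cutoff in Angstrom.
#' @return List of `contact_pairing` objects (one per fragment, possibly
#'   with zero contacts), each holding `fragment_id`, `cutoff`,
#'   `frag_residues` (ordered residue keys of the whole fragment) and
#'   `contacts` (data.frame `frame`, `frag_res`, `rec_res`).
#' @export
pair_contacts <- function(traj, fragments = fragment_partition(traj$system),
                          cutoff = 7) {
  sys <- traj$system
  rec_atoms <- sys$roles$receptor
  if (length(rec_atoms) == 0) stop("receptor role is empty")
  keys <- res_keys(sys)
  rec_res <- unique(keys[rec_atoms])
  rec_groups <- split(rec_atoms, factor(keys[rec_atoms], levels = rec_res))
  nf <- n_frames(traj)
  lapply(names(fragments), function(fid) {
    fa <- fragments[[fid]]
    frag_res <- unique(keys[fa])
    ord <- order(sys$atom$resseq[match(frag_res, keys)])
    frag_res <- frag_res[ord]
    frag_groups <- split(fa, factor(keys[fa], levels = frag_res))
    rows <- vector("list", nf)
    for (f in seq_len(nf)) {
      xyz <- frame_coords(traj, f)
      rc <- t(vapply(rec_groups, function(i) colMeans(xyz[i, , drop = FALSE]),
                     numeric(3)))
      fc <- t(vapply(frag_groups, function(i) colMeans(xyz[i, , drop = FALSE]),
                     numeric(3)))
      d2 <- outer(rowSums(fc^2), rep(1, nrow(rc))) +
        outer(rep(1, nrow(fc)), rowSums(rc^2)) - 2 * fc %*% t(rc)
      hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
      if (nrow(hit) > 0)
        rows[[f]] <- data.frame(frame = f,
                                frag_res = frag_res[hit[, 1]],
                                rec_res = rec_res[hit[, 2]],
                                stringsAsFactors = FALSE)
    }
    contacts <- do.call(rbind, rows)
    if (is.null(contacts))
      contacts <- data.frame(frame = integer(0), frag_res = character(0),
                             rec_res = character(0), stringsAsFactors = FALSE)
    structure(list(fragment_id = fid, cutoff = cutoff,
                   frag_residues = frag_res, contacts = contacts),
              class = "contact_pairing")
  })
}

#' @export
print.contact_pairing <- function(x, ...) {
  cat(sprintf("contact_pairing: fragment %s, %d contacts, %d receptor residues\n",
              x$fragment_id, nrow(x$contacts),
              length(unique(x$contacts$rec_res))))
  invisible(x)
}

#' Split a fragment's contacts into independent interactions
#'
#' A fragment may touch the receptor with two separate stretches while
#' the residues in between never attach; such a pairing is really two
#' interactions. A fragment residue counts as attached when it has at
#' least one paired receptor residue in at least `attach_frac` of the
#' fragment's contact frames. A run of `min_gap` or more consecutive
#' unattached residues between attached stretches splits the pairing;
#' each sub-pairing keeps the receptor residues of its own contacts.
#'
#' @param pairing a `contact_pairing` from [pair_contacts()].
#' @param min_gap minimum unattached run length that forces a split
#'   (default 5 residues).
#' @param attach_frac persistence fraction defining "attached"
#'   (default 0.5 of contact frames).
#' @return List of `contact_pairing` sub-pairings (length 1 when nothing
#'   splits; empty when the pairing has no contacts).
#' @export
split_fragment_interactions <- function(pairing, min_gap = 5,
                                        attach_frac = 0.5) {
  ct <- pairing$contacts
  if (nrow(ct) == 0) return(list())
  contact_frames <- unique(ct$frame)
  res_frames <- tapply(ct$frame, ct$frag_res,
                       function(f) length(unique(f)))
  attached_keys <- names(res_frames)[res_frames / length(contact_frames) >=
                                       attach_frac]
  pos <- match(attached_keys, pairing$frag_residues)
  pos <- sort(pos[!is.na(pos)])
  if (length(pos) == 0) {
    # nothing persistent: keep as one transient pairing
    return(list(pairing))
  }
  seg <- cumsum(c(1, diff(pos) - 1 >= min_gap))
  subs <- lapply(split(pos, seg), function(p) {
    span <- pairing$frag_residues[min(p):max(p)]
    sub_ct <- ct[ct$frag_res %in% span, , drop = FALSE]
    structure(list(fragment_id = pairing$fragment_id,
                   cutoff = pairing$cutoff,
                   frag_residues = span, contacts = sub_ct),
              class = "contact_pairing")
  })
  unname(subs)
}

#' Screen candidate regions by interaction energy
#'
#' For each pairing, the mean total nonbonded energy between the paired
#' receptor residues and the whole fragment is computed over the
#' trajectory; the region survives when the drop reaches `threshold`
#' kcal/mol per paired receptor residue, i.e. mean energy
#' `<= -threshold * n_residues`.
#'
#' @param pairings list of `contact_pairing` objects.
#' @param traj a parameterized `molsys_traj`.
#' @param threshold kcal/mol per receptor residue (default 3).
#' @param cutoff,switch_on nonbonded truncation, see [pair_energy()].
#' @return List of surviving candidates: each a list with `residues`
#'   (receptor residue keys), `fragments` (fragment id), `frag_residues`
#'   and `mean_energy`.
#' @export
screen_by_energy <- function(pairings, traj, threshold = 3,
                             cutoff = 12, switch_on = 10) {
  out <- list()
  for (p in pairings) {
    if (nrow(p$contacts) == 0) next
    region <- sort_res_keys(traj$system, unique(p$contacts$rec_res))
    frag_keys <- frag_residue_keys(traj$system, p$fragment_id)
    es <- energy_series(traj, region, frag_keys,
                        cutoff = cutoff, switch_on = switch_on)
    if (attr(es, "mean") <= -threshold * length(region))
      out[[length(out) + 1]] <- list(residues = region,
                                     fragments = p$fragment_id,
                                     frag_residues = p$frag_residues,
                                     mean_energy = attr(es, "mean"))
  }
  out
}

# all residue keys of a fragment id (ligand chain)
frag_residue_keys <- function(sys, fid) {
  part <- fragment_partition(sys)
  unique(res_keys(sys)[part[[fid]]])
}

# order residue keys by (chain, resseq)
sort_res_keys <- function(sys, keys) {
  k <- res_keys(sys)
  i <- match(keys, k)
  keys[order(sys$atom$chain[i], sys$atom$resseq[i])]
}

#' Merge spatially adjacent candidate sites
#'
#' Two candidates merge when any heavy-atom pair between their receptor
#' residue sets lies within `adjacency_cutoff` in the trajectory-average
#' structure; merging is transitive, so chains of adjacent candidates
#' collapse into one site whose residue and fragment sets are unions.
#' Output is ordered by ascending minimum receptor residue number.
#'
#' @param candidates list of candidates from [screen_by_energy()].
#' @param traj the `molsys_traj` the candidates came from.
#' @param adjacency_cutoff heavy-atom distance in Angstrom (default 5).
#' @return List of merged candidates (`residues`, `fragments`).
#' @export
merge_adjacent_sites <- function(candidates, traj, adjacency_cutoff = 5) {
  n <- length(candidates)
  if (n == 0) return(list())
  sys <- traj$system
  avg <- average_coords(traj)
  heavy <- sys$atom$elem != "H"
  atom_sets <- lapply(candidates, function(cd) {
    i <- atoms_for_residues(sys, cd$residues)
    i[heavy[i]]
  })
  # connected components under the adjacency relation
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (comp[i] == comp[j]) next
    xi <- avg[atom_sets[[i]], , drop = FALSE]
    xj <- avg[atom_sets[[j]], , drop = FALSE]
    d2 <- outer(rowSums(xi^2), rep(1, nrow(xj))) +
      outer(rep(1, nrow(xi)), rowSums(xj^2)) - 2 * xi %*% t(xj)
    if (min(d2) <= adjacency_cutoff^2)
      comp[comp == comp[j]] <- comp[i]
  }
  merged <- lapply(unique(comp), function(cc) {
    members <- candidates[comp == cc]
    list(residues = sort_res_keys(
           sys, unique(unlist(lapply(members, `[[`, "residues")))),
         fragments = sort(unique(unlist(lapply(members, `[[`,
                                               "fragments")))))
  })
  minres <- vapply(merged, function(m) {
    i <- match(m$residues, res_keys(sys))
    min(sys$atom$resseq[i])
  }, numeric(1))
  merged[order(minres)]
}

#' Call binding sites from a trajectory
#'
#' Runs the full pipeline: contact pairing at `contact_cutoff`, fragment
#' splitting, per-residue energy screening, transitive spatial merging,
#' then re-scoring of every merged site. Re-scoring recomputes the
#' energy series against the union of contributing fragments, prunes
#' residues whose own mean interaction energy is weaker than
#' `prune_floor` (very low contributors) or whose ligand-ignored
#' side-chain SASA averages below `min_access_sasa` (inaccessible,
#' buried positions), and drops sites that no longer clear the
#' per-residue energy threshold. Every retained call satisfies the
#' threshold after final re-scoring.
#'
#' @param traj a parameterized `molsys_traj` with receptor and ligand
#'   roles assigned.
#' @param fragments named list of fragment atom index sets (default:
#'   ligand chains).
#' @param contact_cutoff centroid pairing distance, Angstrom (default 7).
#' @param energy_threshold kcal/mol per receptor residue (default 3).
#' @param min_gap,attach_frac splitting parameters, see
#'   [split_fragment_interactions()].
#' @param adjacency_cutoff merge distance, Angstrom (default 5).
#' @param prune_floor per-residue mean energy floor, kcal/mol
#'   (default 0.5: residues with mean energy above -0.5 are pruned).
#' @param min_access_sasa minimum mean ligand-ignored side-chain SASA,
#'   Angstrom^2 (default 5).
#' @param probe probe radius for the per-site RASAS report.
#' @param cutoff,switch_on nonbonded truncation, Angstrom.
#' @param n_points sphere points for SASA.
#' @return Object of class `site_calls`: list of `site_call` objects,
#'   each with `call_id`, `residues`, `fragments`, `mean_energy`,
#'   `sd_energy`, `mean_rasas`, `sd_rasas`, `per_residue_energy`,
#'   `salt_bridges`, and the underlying `energy` and `rasas` series.
#' @export
call_sites <- function(traj, fragments = fragment_partition(traj$system),
                       contact_cutoff = 7, energy_threshold = 3,
                       min_gap = 5, attach_frac = 0.5,
                       adjacency_cutoff = 5, prune_floor = 0.5,
                       min_access_sasa = 5, probe = 1.4,
                       cutoff = 12, switch_on = 10, n_points = 960) {
  sys <- traj$system
  check_parameterized(sys)
  pairings <- pair_contacts(traj, fragments, contact_cutoff)
  subs <- unlist(lapply(pairings, split_fragment_interactions,
                        min_gap = min_gap, attach_frac = attach_frac),
                 recursive = FALSE)
  cands <- screen_by_energy(subs, traj, energy_threshold, cutoff, switch_on)
  merged <- merge_adjacent_sites(cands, traj, adjacency_cutoff)
  calls <- list()
  for (m in merged) {
    frag_keys <- unique(unlist(lapply(m$fragments, frag_residue_keys,
                                      sys = sys)))
    res <- m$residues
    # per-residue mean energy against the contributing fragments
    per_res <- vapply(res, function(r)
      attr(energy_series(traj, r, frag_keys, cutoff, switch_on), "mean"),
      numeric(1))
    res <- res[per_res <= -prune_floor]
    if (length(res) == 0) next
    # accessibility: ligand-ignored side-chain SASA must not vanish
    acc <- vapply(res, function(r) {
      tgt <- sidechain_atoms(sys, r)
      ctx <- setdiff(seq_len(n_atoms(sys)),
                     c(tgt, sys$roles$ligand))
      mean(frame_sasa_total(traj, tgt, ctx, probe, n_points))
    }, numeric(1))
    res <- res[acc >= min_access_sasa]
    if (length(res) == 0) next
    es <- energy_series(traj, res, frag_keys, cutoff, switch_on)
    if (attr(es, "mean") > -energy_threshold * length(res)) next
    rs <- rasas_series(traj, res, probe = probe, n_points = n_points)
    sb <- detect_salt_bridges(traj,
                              group_a = atoms_for_residues(sys, res),
                              group_b = atoms_for_residues(sys, frag_keys))
    calls[[length(calls) + 1]] <- structure(
      list(call_id = length(calls) + 1L, residues = res,
           fragments = m$fragments,
           mean_energy = attr(es, "mean"), sd_energy = attr(es, "sd"),
           mean_rasas = attr(rs, "mean"), sd_rasas = attr(rs, "sd"),
           per_residue_energy = per_res[res],
           salt_bridges = sb, energy = es, rasas = rs),
      class = "site_call")
  }
  structure(calls, class = "site_calls",
            params = list(contact_cutoff = contact_cutoff,
                          energy_threshold = energy_threshold,
                          min_gap = min_gap, attach_frac = attach_frac,
                          adjacency_cutoff = adjacency_cutoff,
                          prune_floor = prune_floor,
                          min_access_sasa = min_access_sasa,
                          probe = probe, cutoff = cutoff,
                          switch_on = switch_on))
}

#' @export
print.site_call <- function(x, ...) {
  cat(sprintf("site call %d: %s\n", x$call_id,
              paste(x$residues, collapse = " ")))
  cat(sprintf("  fragments: %s | energy %.2f +/- %.2f kcal/mol | RASAS %.2f +/- %.2f | %d salt bridge(s)\n",
              paste(x$fragments, collapse = ","), x$mean_energy,
              x$sd_energy, x$mean_rasas, x$sd_rasas,
              nrow(x$salt_bridges)))
  invisible(x)
}

#' @export
print.site_calls <- function(x, ...) {
  cat(length(x), "binding-site call(s)\n")
  for (cl in x) print(cl)
  invisible(x)
}

#' Write site calls as a JSON report
#'
#' One record per call with residues, contributing fragments, mean +/-
#' sd energy and RASAS, per-residue energies, salt bridges and a free
#' `position_note` field.
#'
#' @param calls a `site_calls` object.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_sites_json <- function(calls, path) {
  recs <- lapply(calls, function(x) list(
    call_id = x$call_id,
    residues = x$residues,
    fragments = x$fragments,
    energy = list(mean = x$mean_energy, sd = x$sd_energy),
    rasas = list(mean = x$mean_rasas, sd = x$sd_rasas),
    per_residue_energy = as.list(x$per_residue_energy),
    salt_bridges = as.data.frame(x$salt_bridges),
    position_note = ""))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Per-frame RMSD after optimal superposition
#'
#' Each frame's selected atoms are rigidly superposed onto the reference
#' (least-squares rotation + translation, via `bio3d::fit.xyz`) before
#' the root-mean-square deviation is taken, so rigid-body motion does
#' not register as deviation.
#'
#' @param traj a `molsys_traj`.
#' @param selection integer atom indices or a selection string (see
#'   [select_atoms()]); at least 3 non-collinear atoms.
#' @param reference `m x 3` coordinate matrix for the selected atoms
#'   (default: the first frame).
#' @return Numeric vector of per-frame RMSD values in Angstrom.
#' @export
superposed_rmsd <- function(traj, selection, reference = NULL) {
  sel <- if (is.character(selection)) select_atoms(traj$system, selection)
         else as.integer(selection)
  m <- length(sel)
  if (m < 3) stop("selection must contain at least 3 atoms")
  if (is.null(reference)) reference <- frame_coords(traj, 1)[sel, ]
  if (!is.matrix(reference) || nrow(reference) != m ||
      ncol(reference) != 3)
    stop("reference must be a ", m, " x 3 coordinate matrix")
  fixed <- as.vector(t(reference))
  inds <- bio3d::atom2xyz(seq_len(m))
  vapply(seq_len(n_frames(traj)), function(f) {
    mobile <- as.vector(t(frame_coords(traj, f)[sel, , drop = FALSE]))
    fitted <- bio3d::fit.xyz(fixed, mobile, fixed.inds = inds,
                             mobile.inds = inds)
    sqrt(mean((fixed - as.vector(fitted))^2) * 3)
  }, numeric(1))
}
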