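# Contact pairing, screening, splitting, merging, re-scoring and RMSD.

test_that("centroid pairing is sharp at the 7 Angstrom cutoff", {
  mk <- function(d) {
    sys <- point_system(rbind(c(0, 0, 0), c(d, 0, 0)),
                        chain = c("A", "B"), resseq = 1)
    traj_from_frames(sys, list(coords(sys)))
  }
  near <- pair_contacts(mk(6.9))
  expect_equal(nrow(near[[1]]$contacts), 1)
  expect_equal(near[[1]]$contacts$rec_res, "A:1")
  far <- pair_contacts(mk(7.1))
  expect_equal(nrow(far[[1]]$contacts), 0)
})

test_that("pairing equals a brute-force all-pairs centroid scan", {
  set.seed(31)
  rec_xyz <- matrix(runif(18, 0, 15), 6, 3)
  frag_xyz <- matrix(runif(12, 0, 15), 4, 3)
  sys <- point_system(rbind(rec_xyz, frag_xyz),
                      chain = rep(c("A", "B"), c(6, 4)),
                      resseq = c(1:6, 1:4))
  frames <- list(coords(sys), coords(sys) + matrix(runif(30, -3, 3), 10, 3))
  traj <- traj_from_frames(sys, frames)
  got <- pair_contacts(traj, cutoff = 7)[[1]]$contacts
  want <- do.call(rbind, lapply(seq_along(frames), function(f) {
    x <- frames[[f]]
    do.call(rbind, lapply(1:4, function(j) do.call(rbind, lapply(1:6,
      function(i) {
        if (sqrt(sum((x[6 + j, ] - x[i, ])^2)) <= 7)
          data.frame(frame = f, frag_res = paste0("B:", j),
                     rec_res = paste0("A:", i), stringsAsFactors = FALSE)
      }))))
  }))
  key <- function(df) sort(paste(df$frame, df$frag_res, df$rec_res))
  expect_equal(key(got), key(want))
})

test_that("energy screen keeps regions at 3 kcal/mol per residue or better", {
  # 4 receptor residues, one fragment atom; charge chosen from the
  # Coulomb closed form so the mean energy is exactly the target
  rec_xyz <- cbind(c(0, 2, 4, 6), 0, 0)
  fr_pos <- c(3, 5, 0)
  dists <- sqrt(colSums((t(rec_xyz) - fr_pos)^2))
  q_for <- function(target) target / (-332.0636 * sum(1 / dists))
  run <- function(target) {
    sys <- point_system(rbind(rec_xyz, fr_pos), chain = rep(c("A", "B"),
                                                            c(4, 1)),
                        resseq = c(1:4, 1),
                        charge = c(rep(-1, 4), q_for(target)),
                        epsilon = 0)
    traj <- traj_from_frames(sys, list(coords(sys)))
    pr <- pair_contacts(traj)
    screen_by_energy(pr, traj, threshold = 3)
  }
  kept <- run(-13)   # -13 <= -3 * 4
  expect_length(kept, 1)
  expect_equal(kept[[1]]$residues, paste0("A:", 1:4))
  expect_equal(kept[[1]]$mean_energy, -13, tolerance = 1e-9)
  expect_length(run(-11), 0)  # -11 > -12: dropped
  expect_length(screen_by_energy(list(), NULL), 0)
})

test_that("fragment splitting separates detached interaction stretches", {
  mk_pairing <- function(attached) {
    frag_res <- paste0("B:", 1:32)
    ct <- do.call(rbind, lapply(1:10, function(f)
      data.frame(frame = f, frag_res = paste0("B:", attached),
                 rec_res = ifelse(attached <= 16, "A:1", "A:9"),
                 stringsAsFactors = FALSE)))
    structure(list(fragment_id = "B", cutoff = 7, frag_residues = frag_res,
                   contacts = ct), class = "contact_pairing")
  }
  two <- split_fragment_interactions(mk_pairing(c(1:8, 25:32)))
  expect_length(two, 2)
  expect_equal(unique(two[[1]]$contacts$rec_res), "A:1")
  expect_equal(unique(two[[2]]$contacts$rec_res), "A:9")
  one <- split_fragment_interactions(mk_pairing(1:16))
  expect_length(one, 1)
  # unattached run of min_gap - 1 does not split
  close_gap <- split_fragment_interactions(mk_pairing(c(1:8, 13:20)),
                                           min_gap = 5)
  expect_length(close_gap, 1)
  wide_gap <- split_fragment_interactions(mk_pairing(c(1:8, 14:20)),
                                          min_gap = 5)
  expect_length(wide_gap, 2)
})

test_that("adjacent candidates merge transitively, distant ones do not", {
  sys <- point_system(cbind(c(0, 4, 8, 30), 0, 0), chain = "A",
                      resseq = 1:4)
  traj <- traj_from_frames(sys, list(coords(sys)))
  cand <- function(...) lapply(list(...), function(r)
    list(residues = paste0("A:", r), fragments = "B"))
  chained <- merge_adjacent_sites(cand(1, 2, 3), traj, adjacency_cutoff = 5)
  expect_length(chained, 1)
  expect_equal(chained[[1]]$residues, paste0("A:", 1:3))
  apart <- merge_adjacent_sites(cand(1, 4), traj, adjacency_cutoff = 5)
  expect_length(apart, 2)
  shared <- merge_adjacent_sites(
    list(list(residues = c("A:1", "A:2"), fragments = "B"),
         list(residues = c("A:2", "A:3"), fragments = "C")),
    traj, adjacency_cutoff = 1)
  expect_length(shared, 1)
  expect_setequal(shared[[1]]$fragments, c("B", "C"))
})

test_that("superposed RMSD is zero under rigid motion and matches an SVD oracle", {
  set.seed(13)
  ref <- matrix(rnorm(15, sd = 4), 5, 3)
  sys <- point_system(ref, chain = "A", resseq = 1:5)
  th <- 0.8
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- ref %*% Rz + matrix(c(3, -7, 2), 5, 3, byrow = TRUE)
  noisy <- moved + matrix(rnorm(15, sd = 0.6), 5, 3)
  traj <- traj_from_frames(sys, list(ref, moved, noisy))
  r <- superposed_rmsd(traj, 1:5, reference = ref)
  expect_equal(r[1], 0, tolerance = 1e-10)
  expect_equal(r[2], 0, tolerance = 1e-8)
  # independent Kabsch oracle via SVD: rotate centred Q onto centred P
  kabsch_rmsd <- function(P, Q) {
    Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
    s <- svd(t(Qc) %*% Pc)
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    sqrt(mean(rowSums((Qc %*% R - Pc)^2)))
  }
  expect_equal(r[3], kabsch_rmsd(ref, noisy), tolerance = 1e-8)
  expect_error(superposed_rmsd(traj, 1:2), "at least 3")
  expect_error(superposed_rmsd(traj, 1:5, reference = ref[1:4, ]),
               "coordinate matrix")
})

test_that("call_sites recovers planted events exactly and honors its invariants", {
  sim <- demo_simulation(seed = 301)
  calls <- call_sites(sim$traj)
  expect_length(calls, 3)
  got <- lapply(calls, `[[`, "residues")
  expect_equal(got, sim$expected_sites)
  params <- attr(calls, "params")
  for (x in calls) {
    expect_lte(x$mean_energy,
               -params$energy_threshold * length(x$residues))
    expect_lte(x$mean_rasas, 1)
    expect_true(all(x$per_residue_energy <= -params$prune_floor))
    expect_gt(nrow(x$salt_bridges), 0)
  }
  # idempotence: feeding the calls back through merging changes nothing
  cand <- lapply(calls, function(x)
    list(residues = x$residues, fragments = x$fragments))
  re <- merge_adjacent_sites(cand, sim$traj,
                             adjacency_cutoff = params$adjacency_cutoff)
  expect_equal(lapply(re, `[[`, "residues"), got)
})

test_that("fragments that never approach produce no calls", {
  rec <- make_toy_receptor(40, list(list(residues = 10:13, charge = -1)),
                           seed = 4)
  sim <- make_binding_trajectory(rec, list(list(n_residues = 5, charge = 1)),
                                 list(), n_frames = 6, noise_sd = 0.1,
                                 seed = 5)
  expect_length(call_sites(sim$traj), 0)
})

test_that("events on adjacent patches merge into one multi-fragment site", {
  rec <- make_toy_receptor(60, list(list(residues = 20:23, charge = -1),
                                    list(residues = 24:27, charge = -1)),
                           seed = 6)
  frs <- list(list(n_residues = 6, charge = 1),
              list(n_residues = 6, charge = 1))
  sch <- list(binding_event(1, 20:23, 2, c(4, 14), 16),
              binding_event(2, 24:27, 20, c(22, 32), 34))
  sim <- make_binding_trajectory(rec, frs, sch, n_frames = 36,
                                 noise_sd = 0.15, seed = 9)
  calls <- call_sites(sim$traj)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$residues, res_key("A", 20:27))
  expect_setequal(calls[[1]]$fragments, c("B", "C"))
})

test_that("sensitivity degrades as dwell time shrinks to zero", {
  n_calls_for <- function(dwell_frames) {
    rec <- make_toy_receptor(40, list(list(residues = 15:18, charge = -1)),
                             seed = 8)
    sch <- if (dwell_frames == 0) list() else
      list(binding_event(1, 15:18, 2, c(4, 3 + dwell_frames),
                         min(40, 5 + dwell_frames)))
    sim <- make_binding_trajectory(rec,
                                   list(list(n_residues = 6, charge = 1)),
                                   sch, n_frames = 40, noise_sd = 0.15,
                                   seed = 10)
    length(call_sites(sim$traj))
  }
  counts <- vapply(c(0, 6, 24), n_calls_for, numeric(1))
  expect_equal(counts[1], 0)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[3], 1)
})
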