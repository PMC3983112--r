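# Nonbonded interaction energies and salt-bridge detection.

two_charge_system <- function(d, qa = 1, qb = -1) {
  point_system(rbind(c(0, 0, 0), c(d, 0, 0)), chain = c("A", "B"),
               resseq = 1, charge = c(qa, qb), epsilon = 0.11,
               rmin_half = 2.0)
}

test_that("Coulomb term matches the closed form inside the switch radius", {
  sys <- two_charge_system(5)
  e <- pair_energy(coords(sys), sys, 1, 2)
  expect_equal(unname(e["elec"]), -332.0636 / 5, tolerance = 1e-12)
  # dielectric scales it down
  e2 <- pair_energy(coords(sys), sys, 1, 2, dielectric = 4)
  expect_equal(unname(e2["elec"]), -332.0636 / 20, tolerance = 1e-12)
})

test_that("LJ minimum and cutoff behave exactly", {
  sys <- two_charge_system(4.0, qa = 0, qb = 0)  # r = rmin_ij = 2 + 2
  e <- pair_energy(coords(sys), sys, 1, 2)
  expect_equal(unname(e["vdw"]), -0.11, tolerance = 1e-12)  # -eps_ij
  far <- two_charge_system(12.5)
  ef <- pair_energy(coords(far), far, 1, 2)
  expect_equal(unname(ef), c(0, 0))
  at_cut <- two_charge_system(12)
  ec <- pair_energy(coords(at_cut), at_cut, 1, 2)
  expect_equal(unname(ec), c(0, 0))
})

test_that("energy is continuous across switch-on and cutoff", {
  E <- function(r) {
    sys <- two_charge_system(r)
    sum(pair_energy(coords(sys), sys, 1, 2))
  }
  for (r0 in c(10, 12)) {
    expect_lt(abs(E(r0 - 1e-6) - E(r0 + 1e-6)), 1e-3)
  }
  rs <- seq(9.5, 12.3, by = 0.002)
  es <- vapply(rs, E, numeric(1))
  expect_lt(max(abs(diff(es))), 0.1)  # no jump anywhere on a fine grid
})

test_that("pair energy is symmetric and rigid-motion invariant", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 6
    xyz <- matrix(runif(3 * n, 0, 9), n, 3)
    sys <- point_system(xyz, chain = rep(c("A", "B"), each = 3),
                        resseq = rep(1:3, 2),
                        charge = runif(n, -1, 1),
                        epsilon = runif(n, 0.05, 0.3),
                        rmin_half = runif(n, 1.6, 2.2))
    ab <- pair_energy(xyz, sys, 1:3, 4:6)
    ba <- pair_energy(xyz, sys, 4:6, 1:3)
    expect_equal(ab, ba, tolerance = 1e-12)
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    moved <- xyz %*% (Rx %*% Rz) +
      matrix(runif(3, -20, 20), n, 3, byrow = TRUE)
    expect_equal(pair_energy(moved, sys, 1:3, 4:6), ab, tolerance = 1e-9)
  }
})

test_that("degenerate group inputs error", {
  sys <- two_charge_system(5)
  expect_error(pair_energy(coords(sys), sys, 1:2, 2), "overlap")
  co <- point_system(rbind(c(0, 0, 0), c(0, 0, 0)), chain = c("A", "B"),
                     resseq = 1)
  expect_error(pair_energy(coords(co), co, 1, 2), "zero interatomic")
})

test_that("energy series: distant fragments give zero, stats match the frames", {
  sys <- two_charge_system(30)
  traj <- traj_from_frames(sys, replicate(4, coords(sys), simplify = FALSE))
  es <- energy_series(traj, "A:1", "B:1")
  expect_equal(es$total, rep(0, 4))

  # scripted approach within the switch region: energy decreases
  ds <- c(11.8, 11.2, 10.6, 10.1)
  frames <- lapply(ds, function(d) {
    x <- coords(sys); x[2, 1] <- d; x
  })
  traj2 <- traj_from_frames(sys, frames)
  es2 <- energy_series(traj2, "A:1", "B:1")
  expect_true(all(diff(es2$total) < 0))
  expect_equal(es2$total, es2$elec + es2$vdw)
  expect_equal(attr(es2, "mean"), mean(es2$total))
  expect_equal(attr(es2, "sd"), sd(es2$total))
  expect_error(energy_series(traj2, character(0), "B:1"), "empty")
})

test_that("salt-bridge cutoff is sharp at 3.2 Angstrom", {
  mk <- function(d) {
    atom <- data.frame(serial = 1:2, name = c("NZ", "OE1"),
                       elem = c("N", "O"), chain = c("A", "B"),
                       resseq = 1, resname = c("LYS", "GLU"),
                       x = c(0, d), y = 0, z = 0,
                       radius = c(1.55, 1.52), charge = c(1, -0.5),
                       epsilon = 0.15, rmin_half = 1.8,
                       stringsAsFactors = FALSE)
    sys <- molsys(atom, roles = list(receptor = 1, ligand = 2))
    traj_from_frames(sys, list(coords(sys)))
  }
  hit <- detect_salt_bridges(mk(3.19))
  expect_equal(nrow(hit), 1)
  expect_true(attr(hit, "formed")[1, 1])
  expect_equal(hit$acidic_resname, "GLU")
  expect_equal(hit$basic_name, "NZ")
  miss <- detect_salt_bridges(mk(3.21))
  expect_equal(nrow(miss), 0)
})

test_that("a permanent planted bridge yields one event with occupancy 1", {
  atom <- data.frame(serial = 1:2, name = c("NZ", "OD1"),
                     elem = c("N", "O"), chain = c("A", "B"), resseq = 1,
                     resname = c("LYS", "ASP"), x = c(0, 3.0), y = 0,
                     z = 0, radius = c(1.55, 1.52), charge = c(1, -0.5),
                     epsilon = 0.15, rmin_half = 1.8,
                     stringsAsFactors = FALSE)
  sys <- molsys(atom, roles = list(receptor = 1, ligand = 2))
  traj <- traj_from_frames(sys, replicate(50, coords(sys),
                                          simplify = FALSE))
  ev <- detect_salt_bridges(traj)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$occupancy, 1.0)
  # an intermittent bridge is filtered out by min_occupancy
  frames <- replicate(50, coords(sys), simplify = FALSE)
  for (f in 26:50) frames[[f]][2, 1] <- 6
  traj2 <- traj_from_frames(sys, frames)
  expect_equal(detect_salt_bridges(traj2)$occupancy, 0.5)
  expect_equal(nrow(detect_salt_bridges(traj2, min_occupancy = 0.6)), 0)
})

test_that("electrostatics dominate vdW on charged-patch fixtures", {
  sim <- demo_simulation(seed = 21)
  es <- energy_series(sim$traj, res_key("A", 10:13), res_key("B", 1:6))
  expect_gt(abs(mean(es$elec)), abs(mean(es$vdw)))
  expect_lt(mean(es$elec), 0)
})
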