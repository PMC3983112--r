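# Shared in-code fixtures for the test suite. Everything is generated at
# test time; nothing is read from disk except files the tests write.

# a system of single-atom "residues" with parameters filled in directly;
# chains other than receptor_chains get the ligand role
point_system <- function(xyz, chain, resseq, name = "CA", resname = "GLY",
                         charge = 0, radius = 1.7, epsilon = 0.11,
                         rmin_half = 2.0, receptor_chains = "A") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  name <- rep_len(name, n)
  atom <- data.frame(serial = seq_len(n), name = name,
                     elem = substr(name, 1, 1),
                     chain = rep_len(chain, n),
                     resseq = rep_len(resseq, n),
                     resname = rep_len(resname, n),
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                     radius = rep_len(radius, n),
                     charge = rep_len(charge, n),
                     epsilon = rep_len(epsilon, n),
                     rmin_half = rep_len(rmin_half, n),
                     stringsAsFactors = FALSE)
  rec <- which(atom$chain %in% receptor_chains)
  lig <- setdiff(seq_len(n), rec)
  molsys(atom, roles = c(list(receptor = rec),
                         if (length(lig) > 0) list(ligand = lig)))
}

# trajectory from an explicit list of n x 3 coordinate matrices
traj_from_frames <- function(sys, frames, dt = 0.1) {
  xyz <- array(unlist(frames), dim = c(n_atoms(sys), 3, length(frames)))
  trajectory(sys, xyz, dt * (seq_along(frames) - 1))
}

# the standard synthetic study: a 100-residue receptor with three
# well-separated charged patches and three oppositely charged hexapeptide
# fragments, each dwelling on its patch for ~60% of 45 frames
demo_simulation <- function(seed, noise_sd = 0.2, n_frames = 45) {
  rec <- make_toy_receptor(
    100,
    list(list(residues = 10:13, charge = -1),
         list(residues = 45:48, charge = 1),
         list(residues = 80:83, charge = -1)),
    seed = seed)
  frags <- list(list(n_residues = 6, charge = 1),
                list(n_residues = 6, charge = -1),
                list(n_residues = 6, charge = 1))
  sched <- list(binding_event(1, 10:13, 5, c(10, 35), 40),
                binding_event(2, 45:48, 8, c(14, 38), 42),
                binding_event(3, 80:83, 3, c(9, 33), 37))
  sim <- make_binding_trajectory(rec, frags, sched, n_frames = n_frames,
                                 noise_sd = noise_sd, seed = seed + 100)
  sim$expected_sites <- list(res_key("A", 10:13), res_key("A", 45:48),
                             res_key("A", 80:83))
  sim
}

# write a tiny PDB file from explicit ATOM lines
write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          elem = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resseq, x, y, z, elem)
}
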