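# Structure, trajectory, sequence and parameter I/O.

test_that("read_pdb copies fixed-width fields and round-trips losslessly", {
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 1.234, 2.345, 3.456, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 4.567, 5.678, 6.789, "C"),
    pdb_atom_line(3, "CA", "GLY", "B", 7, -1.500, 0.000, 12.250, "C")))
  sys <- read_pdb(f)
  expect_s3_class(sys, "molsys")
  expect_equal(n_atoms(sys), 3)
  expect_equal(sys$atom$name, c("N", "CA", "CA"))
  expect_equal(sys$atom$resseq, c(1, 1, 7))
  expect_equal(sys$atom$chain, c("A", "A", "B"))
  expect_equal(coords(sys)[3, ], c(x = -1.5, y = 0, z = 12.25))

  out <- tempfile(fileext = ".pdb")
  write_pdb(sys, out)
  back <- read_pdb(out)
  for (col in c("serial", "name", "chain", "resseq", "resname",
                "x", "y", "z"))
    expect_equal(back$atom[[col]], sys$atom[[col]], info = col)
})

test_that("degenerate PDB inputs error clearly", {
  empty <- write_pdb_lines(character(0))
  expect_error(read_pdb(empty), "no atoms")
  expect_error(read_pdb(tempfile()), "not found")
  dup <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1, 0, 0)))
  expect_error(read_pdb(dup), "duplicate")
})

test_that("waters and ions are dropped by default, kept on request", {
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    sub("^ATOM  ", "HETATM",
        pdb_atom_line(2, "O", "HOH", "W", 100, 5, 5, 5, "O"))))
  expect_equal(n_atoms(read_pdb(f)), 1)
  kept <- read_pdb(f, keep_waters = TRUE)
  expect_equal(n_atoms(kept), 2)
  expect_equal(kept$roles$cofactor, 2L)
})

test_that("multi-model trajectories read with assigned times", {
  sys1 <- point_system(rbind(c(0, 0, 0), c(3, 0, 0)), chain = "A",
                       resseq = c(1, 2))
  lines <- unlist(lapply(1:5, function(m) c(
    sprintf("MODEL     %4d", m),
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, m - 1),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3, 0, m - 1),
    "ENDMDL")))
  f <- write_pdb_lines(lines)
  traj <- read_multimodel_trajectory(f, sys1, dt = 0.1)
  expect_equal(n_frames(traj), 5)
  expect_equal(traj$times, seq(0, 0.4, by = 0.1))
  expect_equal(frame_coords(traj, 4)[1, "z"], c(z = 3))

  # model 3 missing an atom is reported by model index
  broken <- lines[-11]  # drop one ATOM line inside MODEL 3
  fb <- write_pdb_lines(broken)
  expect_error(read_multimodel_trajectory(fb, sys1), "model 3")
})

test_that("single-MODEL trajectory equals read_pdb coordinates", {
  f <- write_pdb_lines(c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 1.5, 2.5, 3.5),
    "ENDMDL"))
  sys <- read_pdb(f)
  traj <- read_multimodel_trajectory(f, sys)
  expect_equal(n_frames(traj), 1)
  expect_equal(frame_coords(traj, 1), coords(sys))
})

test_that("trajectory round trip through multi-model PDB is exact to format precision", {
  rec <- make_toy_receptor(20, list(list(residues = 5:8, charge = -1)),
                           seed = 11)
  sim <- make_binding_trajectory(
    rec, list(list(n_residues = 4, charge = 1)),
    list(binding_event(1, 5:8, 1, c(2, 3), 4)),
    n_frames = 4, noise_sd = 0.1, seed = 12)
  f <- tempfile(fileext = ".pdb")
  write_multimodel_trajectory(sim$traj, f)
  back <- read_multimodel_trajectory(f, sim$traj$system)
  expect_equal(n_frames(back), 4)
  expect_equal(back$xyz, sim$traj$xyz, tolerance = 1e-3)
})

test_that("parameter assignment is total, with element fallback logged", {
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "XQ1", "ALA", "A", 2, 5, 0, 0, "C")))
  sys <- read_pdb(f)
  expect_true(anyNA(sys$atom$radius))
  expect_message(sys2 <- assign_parameters(sys), "fallback")
  expect_false(anyNA(sys2$atom$radius))
  expect_equal(sys2$atom$radius, c(1.7, 1.7))  # carbon-class radius
  expect_true(all(c(1, 2) %in% attr(sys2, "param_fallback")))
  expect_error(assign_parameters(sys, element_fallback = FALSE),
               "no parameters")
})

test_that("parameterized lysine side chain carries +1 e", {
  # side-chain atoms of the reduced lysine model
  names <- c("CB", "CG", "CD", "CE", "NZ")
  xyz <- cbind(seq_along(names) * 2.5, 0, 0)
  atom <- data.frame(serial = seq_along(names), name = names,
                     elem = substr(names, 1, 1), chain = "A", resseq = 1,
                     resname = "LYS", x = xyz[, 1], y = xyz[, 2],
                     z = xyz[, 3], stringsAsFactors = FALSE)
  sys <- assign_parameters(molsys(atom), quiet = TRUE)
  expect_equal(sum(sys$atom$charge), 1, tolerance = 1e-6)
})

test_that("alignment reading validates shape and round-trips", {
  f <- tempfile(fileext = ".fasta")
  ids <- paste0("seq", 1:6)
  seqs <- c("ACD-EF", "ACDGEF", "ACD-EF", "ACDAEF", "ACD-EF", "ACDSEF")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), f)
  aln <- read_alignment(f)
  expect_equal(length(aln$ids), 6)
  expect_equal(aln$seqs, seqs)

  out <- tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  back <- read_alignment(out)
  expect_equal(back$ids, aln$ids)
  expect_equal(back$seqs, aln$seqs)

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "ACD"), ragged)
  expect_error(read_alignment(ragged), "ragged")
})

test_that("role assignment keeps roles disjoint and selections parse", {
  sys <- point_system(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)),
                      chain = c("A", "A", "B"), resseq = c(1, 2, 1))
  expect_equal(sys$roles$receptor, c(1L, 2L))
  expect_equal(sys$roles$ligand, 3L)
  sys2 <- set_roles(sys, cofactor = "chain:B")
  expect_equal(sys2$roles$cofactor, 3L)
  expect_length(sys2$roles$ligand, 0)
  expect_equal(select_atoms(sys, "resid:1-1"), c(1L, 3L))
  expect_equal(select_atoms(sys, "chain:A,chain:B"), 1:3)
  expect_error(select_atoms(sys, "name:CA"), "unknown selection")
  expect_error(set_roles(sys, ligand = "chain:Z"), "no atoms")
})
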