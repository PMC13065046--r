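write_pdb_lines <- function(lines) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

test_that("multi-model PDB parses into frames with box from CRYST1", {
  tf <- write_pdb_lines(c(
    "CRYST1   90.000   90.000   90.000  90.00  90.00  90.00 P 1           1",
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  O   HOH W   2       5.000   5.000   5.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.100   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.600   0.000   0.000  1.00  0.00           C",
    "ATOM      3  O   HOH W   2       5.100   5.000   5.000  1.00  0.00           O",
    "ENDMDL", "END"))
  tr <- read_traj_pdb(tf)
  expect_equal(n_frames(tr), 2L)
  expect_equal(n_atoms(tr), 3L)
  expect_equal(unname(tr$box), matrix(90, 2, 3), ignore_attr = TRUE)
  expect_equal(tr$atoms$is_water_oxygen, c(FALSE, FALSE, TRUE))
  expect_equal(unname(frame_coords(tr, 2)[2, 1]), 1.6)
})

test_that("single-model PDB without MODEL records yields one frame", {
  tf <- write_pdb_lines(c(
    "ATOM      1  CA  GLY A   1       0.000   1.000   2.000  1.00  0.00           C",
    "END"))
  tr <- read_traj_pdb(tf)
  expect_equal(n_frames(tr), 1L)
  expect_null(tr$box)
})

test_that("structural and parse errors are specific", {
  mismatched <- write_pdb_lines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL"))
  expect_error(read_traj_pdb(mismatched), "inconsistent atom counts")
  malformed <- write_pdb_lines(c(
    "ATOM      1  CA  GLY A   1       0.000   x.xxx   0.000  1.00  0.00           C"))
  expect_error(read_traj_pdb(malformed), "line 1")
  triclinic <- write_pdb_lines(c(
    "CRYST1   90.000   90.000   90.000  90.00  99.00  90.00 P 1           1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C"))
  expect_error(read_traj_pdb(triclinic), "triclinic")
  expect_error(read_traj_pdb(tempfile()), "not found")
})

test_that("PDB write/read round-trips the model to format precision", {
  sys <- generate_wire_frames(seed = 9, planted_lengths = list(3, c(2, 2)))
  tf <- tempfile(fileext = ".pdb")
  write_traj_pdb(sys$traj, tf)
  back <- read_traj_pdb(tf)
  expect_equal(back$atoms$atom_name, sys$traj$atoms$atom_name)
  expect_equal(back$atoms$residue_id, sys$traj$atoms$residue_id)
  expect_equal(back$atoms$chain_id, sys$traj$atoms$chain_id)
  expect_equal(back$box, sys$traj$box)
  expect_lt(max(abs(back$coords - sys$traj$coords)), 5e-4 + 1e-12)
  # second round trip is the identity on the already-quantised model
  tf2 <- tempfile(fileext = ".pdb")
  write_traj_pdb(back, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("written PDB is readable by an independent parser", {
  sys <- generate_cluster_frames(seed = 4, sizes = c(2, 1), n_atoms = 5)
  tf <- tempfile(fileext = ".pdb")
  write_traj_pdb(sys$traj, tf)
  p <- bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(p$xyz), 3L)
  expect_equal(matrix(p$xyz[2, ], ncol = 3, byrow = TRUE),
               unname(frame_coords(read_traj_pdb(tf), 2)), tolerance = 1e-8)
})

test_that("DCD trajectories load against a PDB topology", {
  sys <- generate_cluster_frames(seed = 4, sizes = c(2, 2), n_atoms = 6)
  top <- tempfile(fileext = ".pdb")
  write_traj_pdb(stride_frames(sys$traj, 4L), top)  # 1-frame topology
  dcd <- tempfile(fileext = ".dcd")
  write_dcd_fixture(dcd, lapply(1:4, function(f) frame_coords(sys$traj, f)))
  tr <- read_traj_dcd(top, dcd)
  expect_equal(n_frames(tr), 4L)
  expect_equal(tr$coords, sys$traj$coords, tolerance = 1e-6)
  expect_null(tr$box)
  # atom-count mismatch between topology and trajectory is refused
  small <- tempfile(fileext = ".pdb")
  sys5 <- generate_cluster_frames(seed = 4, sizes = c(1, 1), n_atoms = 5)
  write_traj_pdb(stride_frames(sys5$traj, 2L), small)
  expect_error(read_traj_dcd(small, dcd), "mismatch")
})

test_that("result tables round-trip through TSV and JSON with provenance", {
  tbl <- result_table(tibble::tibble(frame = 1:3, value = c(1.25, 2.5, NA)),
                      params = list(cutoff = 6, mode = "test"),
                      inputs = "in.pdb", seed = 7L)
  for (fmt in c("tsv", "json")) {
    tf <- tempfile(fileext = paste0(".", fmt))
    write_result(tbl, tf, fmt)
    back <- read_result(tf, fmt)
    expect_equal(as.data.frame(back), as.data.frame(tbl))
    expect_equal(provenance(back)$params$cutoff, 6)
    expect_equal(provenance(back)$seed, 7L)
  }
})

test_that("empty tables are refused unless flagged empty-ok", {
  empty <- result_table(tibble::tibble(a = numeric()))
  tf <- tempfile(fileext = ".tsv")
  expect_error(write_result(empty, tf, "tsv"), "empty")
  expect_silent(write_result(empty, tf, "tsv", empty_ok = TRUE))
  expect_equal(nrow(read_result(tf, "tsv")), 0L)
})

test_that("trajectory invariants are enforced", {
  atoms <- tibble::tibble(atom_name = "CA", element = "C", residue_name = "ALA",
                          residue_id = 1L, chain_id = "A")
  xyz <- array(0, dim = c(2, 1, 3))
  expect_error(trajectory(atoms, xyz, box = c(-1, 5, 5)), "positive")
  expect_error(trajectory(atoms, xyz, frame_times = c(2, 1)), "increasing")
  expect_error(trajectory(atoms[c(1, 1), ], xyz), "rows")
  tr <- trajectory(atoms, xyz, frame_times = c(0.5, 1.0))
  expect_equal(n_frames(stride_frames(tr, 2L)), 1L)
})

test_that("selection mini-language resolves chains, ranges, names and roles", {
  sys <- generate_permeation_system(seed = 2, n_crossed = 1, n_returned = 1,
                                    n_background = 2, n_frames = 8)
  tr <- sys$traj
  expect_equal(parse_selection(tr, "chain P"), select_atoms(tr, chain = "P"))
  expect_setequal(parse_selection(tr, "water"), which(tr$atoms$is_water_oxygen))
  expect_equal(parse_selection(tr, "chain P and resid 1-3 and name C"),
               select_atoms(tr, chain = "P", resid = 1:3, name = "C"))
  expect_length(parse_selection(tr, "all"), n_atoms(tr))
  expect_error(parse_selection(tr, "banana A"), "unknown selection keyword")
})
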