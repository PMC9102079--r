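test_that("frame bookkeeping matches the save-interval arithmetic", {
  expect_identical(frames_per_replica(100, 2), 50000)
  expect_identical(frames_per_replica(1, 1), 1000)
  expect_identical(frames_per_replica(200, 2), 100000)
  expect_error(frames_per_replica(1, 3), "divisible")
  expect_error(frames_per_replica(-1, 2), "positive")
})

test_that("multi-model PDB round-trip preserves topology and coordinates", {
  m <- fx_pentamer()
  tr <- simulate_trajectory(m, scenario("stable", noise_sigma = 0.2, seed = 42),
                            n_frames = 3)
  path <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, path)
  rt <- read_multimodel_pdb(path)
  expect_equal(n_frames(rt), 3)
  expect_identical(rt$topology$atoms$name, m$atoms$name)
  expect_identical(rt$topology$atoms$chain_id, m$atoms$chain_id)
  expect_identical(rt$topology$atoms$res_internal, m$atoms$res_internal)
  expect_identical(rt$topology$atoms$res_serial, m$atoms$res_serial)
  expect_lt(max(abs(rt$coords - tr$coords)), 1e-3 + 1e-12)
})

test_that("a minimal two-model file becomes a two-frame trajectory", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  CA  GLY A   1       0.000   0.000   1.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   1.000  1.00  0.00           C",
    "ENDMDL", "END"), path)
  tr <- read_multimodel_pdb(path)
  expect_equal(n_frames(tr), 2)
  expect_equal(nrow(tr$topology$atoms), 2)
  expect_equal(frame_coords(tr, 2)[1, 3], 1)
})

test_that("inconsistent models and missing chain ids are hard errors", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  CA  GLY A   1       0.000   0.000   1.000  1.00  0.00           C",
    "ENDMDL", "END"), path)
  expect_error(read_multimodel_pdb(path), "MODEL 2")

  path2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY     1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY     2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), path2)
  expect_error(read_multimodel_pdb(path2), "chain")
})

test_that("coordinates that overflow the fixed-width field are rejected", {
  m <- fx_pentamer()
  tr <- simulate_trajectory(m, scenario("stable", noise_sigma = 0, seed = 1),
                            n_frames = 2)
  tr$coords[1, 1, 1] <- 1e6
  expect_error(write_multimodel_pdb(tr, tempfile()), "representable")
})

test_that("a one-frame trajectory writes exactly one MODEL/ENDMDL pair", {
  at <- data.frame(name = "CA", element = "C", res_name = "GLY",
                   chain_id = "A", res_internal = 1L, is_ligand = FALSE)
  m <- fibril_model(at, matrix(c(1, 2, 3), 1))
  tr <- trajectory(m, m$coords)
  path <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(tr, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "MODEL")), 1)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 1)
})

test_that("pentamer numbering conventions form consistent bijections", {
  m <- fx_complex()
  expect_true(validate_pentamer(m))
  at <- m$atoms
  expect_true(all(at$res_abeta[!at$is_ligand] == at$res_internal[!at$is_ligand] + 16))
  key <- unique(paste(at$chain_id, at$res_internal))
  expect_equal(length(key), length(unique(at$res_serial[!duplicated(paste(at$chain_id, at$res_internal))])))
  expect_equal(range(at$res_serial), c(1L, 136L))
  expect_equal(sort(unique(at$res_serial[at$is_ligand])), 131:136)
})

test_that("trajectory invariants are enforced", {
  m <- fx_pentamer()
  two <- array(rep(m$coords, 2), c(nrow(m$atoms), 3, 2))
  expect_error(trajectory(m, two, times = c(2, 1)), "increasing")
  expect_error(trajectory(m, array(0, c(10, 3, 2))), "atom count")
})

test_that("amide hydrogen reconstruction bisects with 1.01 A bond length", {
  n <- c(0, 0, 0); ca <- c(1.4, 0.4, 0); cp <- c(-1.3, 0.5, 0)
  h <- reconstruct_amide_h(n, ca, cp)
  expect_equal(sqrt(sum((h - n)^2)), 1.01, tolerance = 1e-10)
  a1 <- acos(sum((ca - n) * (h - n)) / (sqrt(sum((ca - n)^2)) * 1.01))
  a2 <- acos(sum((cp - n) * (h - n)) / (sqrt(sum((cp - n)^2)) * 1.01))
  expect_equal(a1, a2, tolerance = 1e-10)   # bisecting convention
  expect_equal(abs(h[3]), 0, tolerance = 1e-10)  # planar
})
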