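test_that("structures round-trip through PDB with author numbering and domain maps", {
  spec <- synthetic_spec()
  st <- make_toy_structure(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_pdb(st, rep(0, 120), path)
  dm <- st$domain_map
  back <- read_structure(path, domain_map = dm)
  expect_equal(nrow(back$residues), 120L)
  expect_identical(back$residues$author_resid, st$residues$author_resid)
  # 3 domain-map entries per monomer, HtpG-like architecture
  expect_equal(as.numeric(table(back$domain_map$monomer_id)), c(3, 3))
  expect_identical(residue_domains(back), residue_domains(st))
  # coordinates preserved to PDB precision
  expect_lt(max(abs(back$calpha_coords - st$calpha_coords)), 1e-3)
})

test_that("domain annotation follows author numbering on sparse HtpG-style ranges", {
  # a few residues with HtpG author numbers, annotated 8-228 / 232-493 / 501-624
  lines <- c(sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    1:6, c(8, 100, 240, 480, 510, 624), seq(0, 19, length.out = 6) * 3.8,
    rep(0, 6), rep(0, 6)), "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  dm <- data.frame(monomer_id = "A", domain = c("NTD", "M", "CTD"),
                   author_start = c(8, 232, 501), author_end = c(228, 493, 624))
  st <- read_structure(path, domain_map = dm)
  expect_identical(residue_domains(st),
                   c("NTD", "NTD", "M", "M", "CTD", "CTD"))
})

test_that("degenerate structures are rejected", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
               "END"), path)
  expect_error(read_structure(path), "empty-model")
  expect_error(structure_model(
    data.frame(global_index = 1L, monomer_id = "A", author_resid = 1L,
               resname = "GLY", chain = "A"),
    matrix(0, 1, 3)), "empty-model")
})

test_that("residues lacking a C-alpha are dropped with a warning", {
  lines <- c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  CB  ALA A   3       7.600   0.000   0.000  1.00  0.00",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_warning(st <- read_structure(path), "lack a C-alpha")
  expect_equal(nrow(st$residues), 2L)
})

test_that("trajectories round-trip through DCD and multi-model PDB", {
  spec <- synthetic_spec(n_res_per_monomer = 20L, n_frames = 100L, seed = 9L)
  gen <- generate_ensemble(spec)
  st <- gen$structure
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(gen$ensemble$coords, dcd)
  ens <- read_trajectory(dcd, st)
  expect_equal(dim(ens$coords), c(100L, 120L))   # T=100, N=40
  expect_lt(max(abs(ens$coords - gen$ensemble$coords)), 1e-3)

  pdb <- withr::local_tempfile(fileext = ".pdb")
  sub <- trajectory_ensemble(st, gen$ensemble$coords[1:3, , drop = FALSE])
  write_model_pdb(sub, pdb)
  ens2 <- read_trajectory(pdb, st)
  expect_equal(nrow(ens2$coords), 3L)            # one frame per MODEL record
  expect_lt(max(abs(ens2$coords - sub$coords)), 1e-3)
})

test_that("trajectory/topology mismatches are caught", {
  spec <- synthetic_spec(n_res_per_monomer = 20L, n_frames = 5L, seed = 9L)
  gen <- generate_ensemble(spec)
  dcd <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(gen$ensemble$coords, dcd)
  other <- make_toy_structure(synthetic_spec(n_res_per_monomer = 30L))
  expect_error(read_trajectory(dcd, other), "topology")
  expect_error(trajectory_ensemble(gen$structure,
                                   matrix(0, 0, 120)), "empty-trajectory")
})

test_that("superposition removes exactly rigid motion and is idempotent", {
  st <- tiny_structure(10L)
  ens <- hand_ensemble(st, 6L, sd = 0)           # six copies of the reference
  moved <- rigid_transform_ensemble(ens)
  fit <- superpose_frames(moved, st)
  dev <- sweep(fit$coords, 2, as.numeric(t(st$calpha_coords)))
  expect_lt(max(sqrt(rowSums(dev^2) / 20)), 1e-8)

  noisy <- hand_ensemble(st, 5L, sd = 1.5, seed = 4L)
  once <- superpose_frames(noisy, 1L)
  twice <- superpose_frames(once, 1L)
  expect_lt(max(abs(once$coords - twice$coords)), 1e-10)
})

test_that("superposition preserves intra-frame pairwise distances", {
  st <- tiny_structure(8L)
  ens <- hand_ensemble(st, 4L, sd = 2, seed = 5L)
  fit <- superpose_frames(ens, 1L)
  for (t in 1:4) {
    d0 <- dist(matrix(ens$coords[t, ], ncol = 3, byrow = TRUE))
    d1 <- dist(matrix(fit$coords[t, ], ncol = 3, byrow = TRUE))
    expect_lt(max(abs(d0 - d1)), 1e-10)
  }
})

test_that("least-squares fit matches a brute-force rotation search", {
  set.seed(11)
  n <- 20L
  ref <- matrix(rnorm(3 * n, sd = 4), n, 3)
  frame <- matrix(rnorm(3 * n, sd = 4), n, 3)
  res <- data.frame(global_index = 1:n, monomer_id = "A", author_resid = 1:n,
                    resname = "GLY", chain = "A")
  st <- structure_model(res, ref)
  ens <- trajectory_ensemble(st, matrix(as.numeric(t(frame)), 1))
  fit <- superpose_frames(ens, st)
  fitted_rmsd <- sqrt(sum((matrix(fit$coords[1, ], ncol = 3, byrow = TRUE) -
                           ref)^2) / n)
  # brute force: best RMSD over 1e6 random rotations of the centered frame;
  # RMSD^2(Q) = (|M|^2 + |R|^2 - 2 tr(Q^T M^T R)) / n after centering
  M <- sweep(frame, 2, colMeans(frame))
  R <- sweep(ref, 2, colMeans(ref))
  A <- crossprod(M, R)
  q <- matrix(rnorm(4e6), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # rotation matrix entries (row-major), score = sum(A * Q)
  Qm <- cbind(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
              2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
              2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  scores <- Qm %*% as.numeric(t(A))
  best <- sqrt((sum(M^2) + sum(R^2) - 2 * max(scores)) / n)
  expect_lt(abs(fitted_rmsd - best), 1e-3)
  expect_lte(fitted_rmsd, best + 1e-12)   # the fit is never worse
})

test_that("degenerate references are rejected for fitting", {
  res <- data.frame(global_index = 1:4, monomer_id = "A", author_resid = 1:4,
                    resname = "GLY", chain = "A")
  st <- structure_model(res, cbind(1:4 * 3.8, 0, 0))  # collinear
  ens <- trajectory_ensemble(st, matrix(rnorm(12), 1))
  expect_error(superpose_frames(ens, st), "superposition error")
})

test_that("B-factor maps round-trip at format precision", {
  st <- tiny_structure(10L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bfactor_pdb(st, rep(0, 20), path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  expect_true(all(pdb$atom$b == 0))

  vals <- seq(0, 12, length.out = 20)
  write_bfactor_pdb(st, vals, path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  expect_lt(max(abs(pdb$atom$b - vals)), 1e-2)

  expect_error(write_bfactor_pdb(st, 1:5, path), "dimension error")
})
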