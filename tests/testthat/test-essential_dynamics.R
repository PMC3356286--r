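test_that("the residue correlation map is a proper correlation", {
  st <- tiny_structure(8L)
  ens <- superpose_frames(hand_ensemble(st, 30L, sd = 1, seed = 12L), 1L)
  cv <- covariance_matrix(ens)
  expect_equal(diag(cv$residue_corr), rep(1, 16))
  expect_true(all(cv$residue_corr >= -1 - 1e-12 &
                  cv$residue_corr <= 1 + 1e-12))
  expect_lt(max(abs(cv$residue_corr - t(cv$residue_corr))), 1e-12)
  # covariance is PSD
  ev <- eigen(cv$cov3N, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("the correlation map equals an explicit double-loop computation", {
  st <- tiny_structure(2L)                       # 4 residues
  ens <- hand_ensemble(st, 6L, sd = 1.5, seed = 13L)
  cv <- covariance_matrix(ens)
  # brute force: time averages of 3-vector displacement dot products
  n <- 4L; T <- 6L
  xyz <- array(0, c(T, n, 3))
  for (t in 1:T) xyz[t, , ] <- matrix(ens$coords[t, ], ncol = 3, byrow = TRUE)
  mu <- apply(xyz, c(2, 3), mean)
  oracle <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dots <- numeric(T)
    for (t in 1:T)
      dots[t] <- sum((xyz[t, i, ] - mu[i, ]) * (xyz[t, j, ] - mu[j, ]))
    oracle[i, j] <- mean(dots)
  }
  d <- sqrt(diag(oracle))
  oracle <- oracle / outer(d, d)
  expect_lt(max(abs(cv$residue_corr - oracle)), 1e-10)
})

test_that("the correlation map agrees with an independent DCCM implementation", {
  st <- tiny_structure(6L)
  ens <- superpose_frames(hand_ensemble(st, 25L, sd = 1, seed = 14L), 1L)
  cv <- covariance_matrix(ens)
  ref <- bio3d::dccm.xyz(ens$coords)
  expect_lt(max(abs(cv$residue_corr - unclass(ref))), 1e-8)
})

test_that("PCA satisfies its spectral identities", {
  st <- tiny_structure(6L)
  ens <- superpose_frames(hand_ensemble(st, 40L, sd = 1, seed = 15L), 1L)
  cv <- covariance_matrix(ens)
  md <- pca_decompose(cv)
  # trace conservation and orthonormality
  expect_lt(abs(sum(md$eigenvalues) - sum(diag(cv$cov3N))) /
            sum(diag(cv$cov3N)), 1e-10)
  expect_lt(max(abs(crossprod(md$vectors) - diag(36))), 1e-8)
  expect_true(all(diff(md$eigenvalues) <= 1e-12))
  # covariance reconstruction from all modes
  rec <- md$vectors %*% (md$eigenvalues * t(md$vectors))
  expect_lt(max(abs(rec - cv$cov3N)) / max(abs(cv$cov3N)), 1e-8)
  # rank-1 planted covariance recovers its eigenpair
  set.seed(16); v <- rnorm(36); v <- v / sqrt(sum(v^2))
  md1 <- pca_decompose(7 * tcrossprod(v))
  expect_equal(md1$eigenvalues[1], 7, tolerance = 1e-10)
  expect_lt(max(md1$eigenvalues[-1]), 1e-8 * 7)
  expect_gt(abs(sum(md1$vectors[, 1] * v)), 1 - 1e-10)

  expect_error(pca_decompose(matrix(rnorm(36), 6, 6)), "matrix error")
})

test_that("projections carry the PCA variance structure", {
  st <- tiny_structure(6L)
  ens <- superpose_frames(hand_ensemble(st, 50L, sd = 1, seed = 17L), 1L)
  md <- pca_decompose(covariance_matrix(ens))
  Q <- project_trajectory(ens, md)
  expect_lt(max(abs(colMeans(Q))), 1e-10)
  # var(q_k) = lambda_k (population convention, same-ensemble identity)
  v <- colMeans(Q^2)
  keep <- md$eigenvalues > 1e-10
  expect_lt(max(abs(v[keep] - md$eigenvalues[keep]) /
                md$eigenvalues[keep]), 1e-6)
  # cross-mode projections are uncorrelated
  for (k in 1:3) for (l in (k + 1):4)
    expect_lt(abs(mean(Q[, k] * Q[, l])),
              1e-8 * sqrt(md$eigenvalues[k] * md$eigenvalues[l]) + 1e-12)
  # completeness: all modes reconstruct the centered trajectory
  X <- sweep(ens$coords, 2, colMeans(ens$coords))
  expect_lt(max(abs(Q %*% t(md$vectors) - X)), 1e-8)
  expect_error(project_trajectory(ens, md, k = 100L), "index error")
})

test_that("single-mode filtered correlation is the eigenvector block cosine", {
  set.seed(18)
  n <- 10L
  v <- rnorm(3 * n)
  v <- v / sqrt(sum(v^2))
  for (lambda in c(0.5, 4, 40)) {               # eigenvalue cancels exactly
    md <- as_mode_set(cbind(v), lambda)
    cc <- mode_filtered_correlation(md, 1L)
    vb <- matrix(v, ncol = 3, byrow = TRUE)
    cosine <- tcrossprod(vb) /
      outer(sqrt(rowSums(vb^2)), sqrt(rowSums(vb^2)))
    expect_lt(max(abs(cc - cosine)), 1e-12)
  }
})

test_that("mode-filtered correlation equals the correlation of the reconstructed trajectory", {
  set.seed(19)
  n <- 8L; T <- 200L; lambda <- c(6, 2)
  V <- qr.Q(qr(matrix(rnorm(3 * n * 2), 3 * n, 2)))
  # amplitudes with exact empirical covariance diag(lambda)
  Q <- qr.Q(qr(scale(matrix(rnorm(T * 2), T, 2), scale = FALSE)))
  Q <- Q * rep(sqrt(T * lambda), each = T)
  st <- tiny_structure(4L)
  recon <- trajectory_ensemble(st, Q %*% t(V) +
                               rep(1, T) %o% as.numeric(t(st$calpha_coords)))
  brute <- covariance_matrix(recon)$residue_corr
  md <- as_mode_set(V, lambda)
  cc <- mode_filtered_correlation(md, 1:2)
  expect_lt(max(abs(cc - brute)), 1e-6)
})

test_that("planted anti-correlated domains show in the filtered map", {
  tr <- planted_truth(synthetic_spec())
  md <- as_mode_set(tr$true_modes, tr$true_eigenvalues)
  cc <- mode_filtered_correlation(md, 1:2)
  st <- tr$structure
  doms <- residue_domains(st)
  mono <- st$residues$monomer_id
  ntd <- which(doms == "NTD" & mono == "A")
  ctd <- which(doms == "CTD" & mono == "A")
  m <- which(doms == "M" & mono == "A")
  expect_lt(mean(cc[ntd, ctd]), 0)
  expect_gt(mean(cc[ntd, m]), 0)
})

test_that("domain-block summaries match a nested-loop average", {
  st <- tiny_structure(9L)
  ens <- superpose_frames(hand_ensemble(st, 30L, sd = 1, seed = 20L), 1L)
  cc <- covariance_matrix(ens)$residue_corr
  blocks <- domain_block_correlation(cc, st)
  doms <- residue_domains(st)
  mono <- st$residues$monomer_id
  for (r in sample(nrow(blocks), 6)) {
    ia <- which(mono == blocks$monomer_a[r] & doms == blocks$domain_a[r])
    ib <- which(mono == blocks$monomer_b[r] & doms == blocks$domain_b[r])
    acc <- c()
    for (i in ia) for (j in ib) acc <- c(acc, cc[i, j])
    expect_lt(abs(blocks$mean[r] - mean(acc)), 1e-12)
  }
  # identity matrix: off-diagonal blocks centred on zero, diagonal positive
  idblocks <- domain_block_correlation(diag(18), st)
  diag_blocks <- idblocks$monomer_a == idblocks$monomer_b &
    idblocks$domain_a == idblocks$domain_b
  expect_true(all(idblocks$mean[diag_blocks] > 0))
  expect_true(all(abs(idblocks$mean[!diag_blocks]) < 1e-12))
})

test_that("NMSF profiles conserve the spectrum and normalize per monomer", {
  spec <- synthetic_spec(n_frames = 300L, seed = 22L)
  gen <- generate_ensemble(spec)
  fit <- superpose_frames(gen$ensemble, 1L)
  cv <- covariance_matrix(fit)
  md <- pca_decompose(cv)
  prof_all <- nmsf_profile(md, seq_len(md$n_modes), gen$structure)
  expect_lt(abs(sum(prof_all$msf_raw) - sum(diag(cv$cov3N))), 1e-8)
  prof <- nmsf_profile(md, 1:2, gen$structure)
  expect_equal(as.numeric(tapply(prof$nmsf, prof$monomer, max)), c(1, 1))
  expect_true(all(prof$nmsf >= 0))
})

test_that("RMSIP measures subspace agreement", {
  set.seed(23)
  V <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  expect_equal(subspace_overlap(V[, 1:2], V[, 1:2], 2), 1, tolerance = 1e-12)
  expect_equal(subspace_overlap(V[, 1:2], V[, 3:4], 2), 0, tolerance = 1e-12)
  expect_error(subspace_overlap(V, V[1:27, ], 2), "dimension")
})

test_that("correlation maps are invariant under global rigid transforms", {
  st <- tiny_structure(8L)
  ens <- hand_ensemble(st, 25L, sd = 1, seed = 24L)
  c0 <- covariance_matrix(superpose_frames(ens, 1L))$residue_corr
  moved <- rigid_transform_ensemble(ens, angle = 0.9, shift = c(2, 2, -7))
  c1 <- covariance_matrix(superpose_frames(moved, 1L))$residue_corr
  expect_lt(max(abs(c0 - c1)), 1e-10)
})
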