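test_that("profile smoothing is a per-monomer moving average with identity window", {
  prof <- profile_df(c(rnorm(20), rnorm(20) + 5), n_per = 20L)
  expect_equal(smooth_profile(prof, 1L)$nmsf, prof$nmsf)
  const <- profile_df(rep(2, 40), n_per = 20L)
  expect_equal(smooth_profile(const, 5L)$nmsf, const$nmsf)
  # a linear ramp is unchanged in the interior of each monomer
  ramp <- profile_df(c(1:20, 20:1) / 10, n_per = 20L)
  sm <- smooth_profile(ramp, 5L)
  expect_equal(sm$nmsf[3:18], ramp$nmsf[3:18])
  expect_equal(sm$nmsf[23:38], ramp$nmsf[23:38])
  # no bleed across the monomer boundary: interior slopes preserved
  expect_error(smooth_profile(prof, 4L), "parameter error")
})

test_that("stationary points land on the analytic extrema of sinusoids", {
  n <- 60L
  u <- (seq_len(n) - 1) / (n - 1)
  f <- sin(3 * 2 * pi * u)                       # 3 full periods per monomer
  prof <- profile_df(rep(f, 2), n_per = n)
  sm <- smooth_profile(prof, 5L)
  pts <- find_stationary_points(sm, 5L, 0.05)
  for (offset in c(0L, 60L)) {
    mx <- sort(pts$maxima[pts$maxima > offset & pts$maxima <= offset + n] - offset)
    mn <- sort(pts$minima[pts$minima > offset & pts$minima <= offset + n] - offset)
    # analytic antinodes: u = (k + 1/4)/3 and (k + 3/4)/3
    expect_length(mx, 3L)
    expect_true(all(abs(mx - (c(1, 5, 9) / 12 * (n - 1) + 1)) <= 1))
    expect_length(mn, 3L)
    expect_true(all(abs(mn - (c(3, 7, 11) / 12 * (n - 1) + 1)) <= 1))
    # minima and maxima alternate
    both <- sort(c(mx, mn))
    expect_true(all(diff(both %in% mx) != 0))
  }
})

test_that("monotone profiles yield no interior extrema", {
  prof <- profile_df(rep(seq(0, 1, length.out = 40), 2), n_per = 40L)
  pts <- find_stationary_points(smooth_profile(prof, 5L), 5L, 0.05)
  expect_length(pts$minima, 0L)
  expect_length(pts$maxima, 0L)
})

test_that("detected extrema are invariant under affine rescaling", {
  set.seed(31)
  for (rep in 1:100) {
    f <- cumsum(rnorm(50))
    prof <- profile_df(f, n_per = 50L)
    a <- runif(1, 0.1, 10); b <- rnorm(1, 0, 5)
    prof2 <- profile_df(a * f + b, n_per = 50L)
    p1 <- find_stationary_points(smooth_profile(prof, 5L), 5L, 0.05)
    p2 <- find_stationary_points(smooth_profile(prof2, 5L), 5L, 0.05)
    expect_identical(p1$minima, p2$minima)
    expect_identical(p1$maxima, p2$maxima)
  }
})

test_that("a single planted flexibility peak is called as one NTD maximum", {
  # the dominant default mode peaks inside the NTD; with that mode alone the
  # smoothed profile carries exactly one recognition maximum in the NTD
  spec <- synthetic_spec(mode_shapes = default_mode_shapes()[1],
                         eigenvalues = 10, seed = 33L)
  gen <- generate_ensemble(spec)
  md <- pca_decompose(covariance_matrix(superpose_frames(gen$ensemble, 1L)))
  prof <- nmsf_profile(md, 1L, gen$structure)
  pts <- find_stationary_points(smooth_profile(prof, 5L), 5L, 0.05)
  doms <- residue_domains(gen$structure)
  for (m in c("A", "B")) {
    in_ntd <- pts$maxima[doms[pts$maxima] == "NTD" &
                         gen$structure$residues$monomer_id[pts$maxima] == m]
    expect_length(in_ntd, 1L)
  }
})

test_that("inflection points sit at analytic curvature sign changes", {
  n <- 41L
  x <- seq_len(n)
  cubic <- profile_df((x - 21)^3 / 1000, n_per = n)
  infl <- find_inflection_points(cubic, window = 1L, min_run = 2L)
  expect_length(infl, 1L)
  expect_lte(abs(infl - 21L), 1L)

  quad <- profile_df((x - 21)^2 / 100, n_per = n)   # strictly convex
  expect_length(find_inflection_points(quad, window = 1L, min_run = 2L), 0L)

  u <- (x - 1) / (n - 1)
  sine <- profile_df(sin(2 * 2 * pi * u), n_per = n)
  infl_s <- find_inflection_points(sine, window = 1L, min_run = 2L)
  # oracle: exhaustive scan of the analytic curvature -sin(4 pi u)
  curv <- -sin(2 * 2 * pi * u)
  crossings <- which(sign(curv[-n]) * sign(curv[-1]) < 0 |
                     abs(curv[-n]) < 1e-12)
  expect_true(all(vapply(infl_s, function(i)
    min(abs(i - crossings)) <= 1, logical(1))))
  expect_gte(length(infl_s), 3L)
  expect_error(find_inflection_points(sine, window = 1L, min_run = 0L),
               "parameter error")
})

test_that("coupling partners respect domain structure and thresholds", {
  st <- tiny_structure(9L)                       # domains of 3 per monomer
  n <- 18L
  expect_length(unlist(coupling_partners(5L, diag(n), st, 0.5)), 0L)
  # hand-built block signs: NTD(A) anti-correlated with CTD(A), silent vs M
  cc <- diag(n)
  doms <- residue_domains(st)
  mono <- st$residues$monomer_id
  ntdA <- which(doms == "NTD" & mono == "A")
  ctdA <- which(doms == "CTD" & mono == "A")
  cc[ntdA, ctdA] <- -0.8; cc[ctdA, ntdA] <- -0.8
  cp <- coupling_partners(ntdA[2], cc, st, 0.5)
  expect_setequal(cp$negative, ctdA)
  expect_length(cp$positive, 0L)
  # threshold 0: every other-domain residue with defined correlation
  cc0 <- cc
  cc0[cc0 == 0] <- 0.01
  cp0 <- coupling_partners(ntdA[2], cc0, st, 0)
  expect_setequal(c(cp0$positive, cp0$negative),
                  which(mono != "A" | doms != "NTD"))
})

test_that("motif classification spans, classes and coupling flags are coherent", {
  tr <- planted_truth(synthetic_spec())
  st <- tr$structure
  md <- as_mode_set(tr$true_modes, tr$true_eigenvalues)
  cc <- mode_filtered_correlation(md, 1:2)
  prof <- nmsf_profile(md, 1:2, st)
  sm <- smooth_profile(prof, 5L)
  pts <- find_stationary_points(sm, 5L, 0.05)
  infl <- find_inflection_points(sm, 5L, 2L)
  motifs <- classify_motifs(pts, infl, cc, st, threshold = 0.5,
                            span_radius = 5L)
  expect_true(all(motifs$start <= motifs$seed & motifs$seed <= motifs$end))
  expect_true(all(motifs$class %in%
                  c("anchor", "recognition", "turning_point")))
  # seeds typed by their origin
  expect_setequal(motifs$seed[motifs$class == "anchor"], pts$minima)
  expect_setequal(motifs$seed[motifs$class == "recognition"], pts$maxima)
  expect_setequal(motifs$seed[motifs$class == "turning_point"], infl)
  # spans never cross monomer (or domain) boundaries
  mono <- st$residues$monomer_id
  doms <- residue_domains(st)
  for (r in seq_len(nrow(motifs))) {
    span <- motifs$start[r]:motifs$end[r]
    expect_length(unique(mono[span]), 1L)
    expect_length(unique(doms[span]), 1L)
  }
  # the mid-CTD hinge anchor is coupled across domains (planted NTD-CTD
  # anti-correlation exceeds the 0.5 threshold for some pairs)
  anchors <- motifs[motifs$class == "anchor", ]
  expect_gte(nrow(anchors), 1L)
  expect_true(any(anchors$inter_domain_flag))
})

test_that("a flat profile yields no motifs", {
  st <- tiny_structure(10L)
  prof <- profile_df(rep(1, 20), n_per = 10L)
  prof$monomer <- st$residues$monomer_id
  sm <- smooth_profile(prof, 3L)
  pts <- find_stationary_points(sm, 3L, 0.05)
  motifs <- classify_motifs(pts, integer(0), diag(20), st)
  expect_equal(nrow(motifs), 0L)
})
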