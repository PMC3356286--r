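#' Specification of a synthetic two-protomer ensemble
#'
#' Defines a Gaussian linear-mode generative model for a C-alpha dimer
#' ensemble: a reference geometry, a few orthonormal displacement modes with
#' prescribed amplitudes (eigenvalues, in Angstrom^2), isotropic
#' per-coordinate noise, optional per-frame rigid-body jitter, and optional
#' planted two-state salt bridges of prescribed occupancy.  The same spec
#' yields closed-form ground truth via [planted_truth()], so every
#' downstream stage of the pipeline can be validated against it.
#'
#' The default spec is the package's reference study condition: 2 monomers x
#' 60 residues (domain fractions NTD 0.35 / M 0.40 / CTD 0.25), three modes
#' with eigenvalues 10, 3, 1 Angstrom^2, noise sigma 0.3 Angstrom, 1000
#' frames, seed 42.  Mode 1 loads with opposite signs on the NTD and CTD of
#' each monomer (and opposite signs across monomers), planting the
#' anti-correlated NTD--CTD / positively correlated NTD--M block structure
#' characteristic of open Hsp90-family dimers.
#'
#' @param n_res_per_monomer residues per monomer (>= 12).
#' @param domain_fractions three fractions (NTD, M, CTD) summing to 1.
#' @param mode_shapes list of [mode_shape()] descriptors.
#' @param eigenvalues per-mode amplitudes lambda_k (Angstrom^2), strictly
#'   decreasing and positive.
#' @param noise_sigma isotropic per-coordinate noise sd (Angstrom).
#' @param n_frames number of frames T.
#' @param seed integer seed; fully determines the output.
#' @param planted_bridges optional data.frame with columns `res_i`, `res_j`
#'   (global residue indices), `occupancy`, `bound_distance`,
#'   `unbound_distance` (Angstrom).
#' @param jitter_translation_sd per-frame random rigid translation sd
#'   (Angstrom); emulates the unremoved global motion of raw MD frames.
#' @param jitter_rotation_sd per-frame random rigid rotation sd (degrees).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_res_per_monomer = 60L,
                           domain_fractions = c(NTD = 0.35, M = 0.40, CTD = 0.25),
                           mode_shapes = default_mode_shapes(),
                           eigenvalues = c(10, 3, 1),
                           noise_sigma = 0.3,
                           n_frames = 1000L,
                           seed = 42L,
                           planted_bridges = NULL,
                           jitter_translation_sd = 0.5,
                           jitter_rotation_sd = 1) {
  if (n_res_per_monomer < 12L)
    stop("spec error: n_res_per_monomer must be >= 12")
  if (length(domain_fractions) != 3L ||
      abs(sum(domain_fractions) - 1) > 1e-8)
    stop("spec error: domain_fractions must be 3 fractions summing to 1")
  if (is.null(names(domain_fractions)))
    names(domain_fractions) <- c("NTD", "M", "CTD")
  if (length(mode_shapes) != length(eigenvalues))
    stop("spec error: one eigenvalue per mode shape")
  if (length(eigenvalues) > 0) {
    if (any(eigenvalues < 0)) stop("spec error: eigenvalues must be >= 0")
    pos <- eigenvalues[eigenvalues > 0]
    if (length(pos) > 1 && any(diff(pos) >= 0))
      stop("spec error: positive eigenvalues must be strictly decreasing")
    if (any(diff(eigenvalues) > 0))
      stop("spec error: eigenvalues must be non-increasing")
  }
  if (noise_sigma < 0) stop("spec error: noise_sigma must be >= 0")
  if (!is.null(planted_bridges)) {
    planted_bridges <- as.data.frame(planted_bridges)
    stopifnot(all(c("res_i", "res_j", "occupancy") %in%
                  names(planted_bridges)))
    if (is.null(planted_bridges$bound_distance))
      planted_bridges$bound_distance <- 3.0
    if (is.null(planted_bridges$unbound_distance))
      planted_bridges$unbound_distance <- 7.0
    if (any(planted_bridges$bound_distance >=
            planted_bridges$unbound_distance))
      stop("spec error: bound_distance must be < unbound_distance")
    if (any(planted_bridges$occupancy < 0 | planted_bridges$occupancy > 1))
      stop("spec error: occupancy must be in [0, 1]")
  }
  obj <- list(n_res_per_monomer = as.integer(n_res_per_monomer),
              domain_fractions = domain_fractions,
              mode_shapes = mode_shapes,
              eigenvalues = eigenvalues,
              noise_sigma = noise_sigma,
              n_frames = as.integer(n_frames),
              seed = as.integer(seed),
              planted_bridges = planted_bridges,
              jitter_translation_sd = jitter_translation_sd,
              jitter_rotation_sd = jitter_rotation_sd)
  class(obj) <- "synthetic_spec"
  obj
}

#' Sinusoidal displacement-field descriptor for one planted mode
#'
#' The scalar field at residue j of monomer m (fractional position
#' u = (j-1)/(n-1) along the monomer) is
#' `monomer_signs[m] * domain_weights[domain] * sin(pi * (wavenumber * u + phase))`,
#' applied along a fixed Cartesian axis.  Signed domain weights plant
#' correlation / anti-correlation between domain blocks; monomer signs plant
#' inter-protomer (anti-)correlation.
#'
#' @param wavenumber half-periods of the sinusoid across one monomer.
#' @param axis displacement direction: "x", "y" or "z".
#' @param phase phase offset in half-period units.
#' @param domain_weights named weights for NTD/M/CTD (may be negative).
#' @param monomer_signs length-2 sign vector across the two monomers.
#' @return a `mode_shape` descriptor.
#' @export
mode_shape <- function(wavenumber, axis = "x", phase = 0,
                       domain_weights = c(NTD = 1, M = 1, CTD = 1),
                       monomer_signs = c(1, 1)) {
  stopifnot(axis %in% c("x", "y", "z"), length(monomer_signs) == 2L)
  structure(list(wavenumber = wavenumber, axis = axis, phase = phase,
                 domain_weights = domain_weights,
                 monomer_signs = monomer_signs),
            class = "mode_shape")
}

#' @rdname synthetic_spec
#' @export
default_mode_shapes <- function() {
  list(
    # dominant opening/closing mode: peaks inside the NTD, declines across
    # the M-domain, crosses zero at the M/CTD boundary (a planted
    # inter-domain hinge) and moves the CTD in anti-phase; the two protomers
    # move in anti-phase with each other
    mode_shape(wavenumber = 1, phase = 0.25, axis = "x",
               monomer_signs = c(1, -1)),
    # second mode: one full sine period across the CTD (zero net
    # displacement per monomer, so the field is nearly free of rigid-body
    # content), silent elsewhere; plants two mobile CTD lobes flanking a
    # mid-CTD node
    mode_shape(wavenumber = 8, phase = 0, axis = "y",
               domain_weights = c(NTD = 0, M = 0, CTD = 1),
               monomer_signs = c(1, -1)),
    # third mode: higher-wavenumber ripple, anti-phase across protomers
    mode_shape(wavenumber = 3, axis = "z", monomer_signs = c(1, -1)))
}

# domain residue counts from fractions, summing exactly to n
domain_counts <- function(n, fractions) {
  cum <- round(cumsum(fractions) * n)
  counts <- diff(c(0, cum))
  names(counts) <- names(fractions)
  counts
}

#' Build the toy two-protomer reference structure
#'
#' Each monomer is laid out as a smooth helical arc with exact 3.8 Angstrom
#' consecutive C-alpha spacing; the second monomer is the first rotated 180
#' degrees about z and offset in x, giving a non-intersecting side-by-side
#' dimer.  Author residue numbering restarts at 1 in each monomer (chains
#' A and B); the domain map follows `domain_fractions`.
#'
#' @param spec a `synthetic_spec`.
#' @return a `structure_model`.
#' @export
make_toy_structure <- function(spec) {
  n <- spec$n_res_per_monomer
  radius <- 12
  dtheta <- 0.25
  rise <- sqrt(3.8^2 - (2 * radius * sin(dtheta / 2))^2)
  j <- seq_len(n) - 1L
  helix <- cbind(radius * cos(j * dtheta),
                 radius * sin(j * dtheta),
                 j * rise)
  helix <- sweep(helix, 2, colMeans(helix))
  m2 <- helix %*% diag(c(-1, -1, 1))         # 180 degrees about z
  m2[, 1] <- m2[, 1] + 30
  coords <- rbind(helix, m2)
  counts <- domain_counts(n, spec$domain_fractions)
  residues <- data.frame(
    global_index = seq_len(2L * n),
    monomer_id = rep(c("A", "B"), each = n),
    author_resid = rep(seq_len(n), 2L),
    resname = "GLY",
    chain = rep(c("A", "B"), each = n),
    stringsAsFactors = FALSE)
  ends <- cumsum(counts)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  domain_map <- data.frame(
    monomer_id = rep(c("A", "B"), each = 3L),
    domain = rep(names(counts), 2L),
    author_start = rep(starts, 2L),
    author_end = rep(ends, 2L),
    stringsAsFactors = FALSE)
  structure_model(residues, coords, domain_map)
}

# 3N-dim rigid-body subspace of a reference geometry: 3 translations plus
# 3 infinitesimal rotations about the centroid, orthonormalized
rigid_basis <- function(calpha_coords) {
  n <- nrow(calpha_coords)
  cen <- sweep(calpha_coords, 2, colMeans(calpha_coords))
  B <- matrix(0, 3 * n, 6)
  for (a in 1:3) B[seq(a, 3 * n, by = 3), a] <- 1
  axes <- diag(3)
  for (a in 1:3) {
    rot <- t(apply(cen, 1, function(r) c(axes[a, 2] * r[3] - axes[a, 3] * r[2],
                                         axes[a, 3] * r[1] - axes[a, 1] * r[3],
                                         axes[a, 1] * r[2] - axes[a, 2] * r[1])))
    B[, 3 + a] <- as.numeric(t(rot))
  }
  qr.Q(qr(B))
}

# evaluate one mode_shape descriptor as a raw 3N field on the structure;
# domain weights are tapered by a short moving average within each monomer
# so the field (and hence the planted NMSF profile) is smooth across domain
# boundaries rather than stepping
evaluate_mode_field <- function(shape, structure, spec, taper = 5L) {
  res <- structure$residues
  n_mono <- spec$n_res_per_monomer
  doms <- residue_domains(structure)
  monomers <- unique(res$monomer_id)
  u <- (res$author_resid - 1) / (n_mono - 1)
  msign <- shape$monomer_signs[match(res$monomer_id, monomers)]
  w <- shape$domain_weights[doms]
  w[is.na(w)] <- 0
  half <- taper %/% 2L
  for (m in monomers) {
    idx <- which(res$monomer_id == m)
    wm <- w[idx]
    sm <- vapply(seq_along(wm), function(i)
      mean(wm[max(1, i - half):min(length(wm), i + half)]), numeric(1))
    # end envelope: fields die off smoothly at the chain termini, so the
    # planted profile has no extrema at the monomer edges and the modes
    # carry little net rotation
    j <- seq_along(wm)
    env <- pmin(1, (j - 1) / taper, (length(wm) - j) / taper)
    w[idx] <- sm * env
  }
  f <- msign * w * sin(pi * (shape$wavenumber * u + shape$phase))
  v <- numeric(3L * nrow(res))
  axis_off <- match(shape$axis, c("x", "y", "z"))
  v[seq(axis_off, length(v), by = 3L)] <- f
  v
}

#' Orthonormal planted mode basis from the shape descriptors
#'
#' Evaluates each shape descriptor on the reference structure, projects the
#' fields out of the 6-dimensional rigid-body subspace (so planted modes are
#' purely internal motions, as recovered modes of a superposed ensemble must
#' be), and orthonormalizes them by Gram--Schmidt in the 3N space, keeping
#' the descriptor order.
#'
#' @param structure the reference `structure_model`.
#' @param spec the `synthetic_spec` (uses `mode_shapes`).
#' @return 3N x K matrix of orthonormal mode vectors.
#' @export
build_mode_basis <- function(structure, spec) {
  K <- length(spec$mode_shapes)
  if (K < 1L) stop("spec error: need at least one mode shape")
  n3 <- 3L * n_residues(structure)
  Fmat <- vapply(spec$mode_shapes, evaluate_mode_field, numeric(n3),
                 structure = structure, spec = spec)
  R <- rigid_basis(structure$calpha_coords)
  Fmat <- Fmat - R %*% (t(R) %*% Fmat)
  V <- matrix(0, n3, K)
  for (k in seq_len(K)) {
    v <- Fmat[, k]
    if (k > 1L) v <- v - V[, 1:(k - 1), drop = FALSE] %*%
        (t(V[, 1:(k - 1), drop = FALSE]) %*% v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8 * sqrt(sum(Fmat[, k]^2)) || nv == 0)
      stop("basis error: mode field ", k,
           " is linearly dependent on earlier fields")
    V[, k] <- v / nv
  }
  V
}

# small random rotation matrix (angle ~ N(0, sd_deg) about a random axis)
random_small_rotation <- function(sd_deg) {
  ang <- stats::rnorm(1, 0, sd_deg * pi / 180)
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Sample a synthetic trajectory from the planted Gaussian mode model
#'
#' Frame t is `reference + sum_k sqrt(lambda_k) eta_kt v_k + eps_t`, with
#' `eta_kt` i.i.d. standard normal amplitudes and `eps_t` i.i.d. isotropic
#' normal noise, followed (by default) by a small random rigid-body jitter
#' per frame so that, like raw MD frames, the ensemble must be superposed
#' before covariance analysis.  Fully determined by `spec$seed`.
#'
#' @param structure reference `structure_model` from [make_toy_structure()].
#' @param true_modes 3N x K orthonormal basis from [build_mode_basis()].
#' @param spec the `synthetic_spec`.
#' @return a `trajectory_ensemble` (frames not superposed).
#' @export
sample_trajectory <- function(structure, true_modes, spec) {
  if (spec$n_frames < 2L) stop("spec error: need n_frames >= 2")
  n3 <- 3L * n_residues(structure)
  K <- ncol(true_modes)
  ref <- as.numeric(t(structure$calpha_coords))
  set.seed(spec$seed)
  eta <- matrix(stats::rnorm(spec$n_frames * K), spec$n_frames, K)
  disp <- eta %*% (t(true_modes) * sqrt(spec$eigenvalues))
  if (spec$noise_sigma > 0)
    disp <- disp + matrix(stats::rnorm(spec$n_frames * n3,
                                       sd = spec$noise_sigma),
                          spec$n_frames, n3)
  coords <- sweep(disp, 2, ref, `+`)
  if (spec$jitter_rotation_sd > 0 || spec$jitter_translation_sd > 0) {
    cen <- colMeans(structure$calpha_coords)
    for (t in seq_len(spec$n_frames)) {
      M <- matrix(coords[t, ], ncol = 3, byrow = TRUE)
      U <- random_small_rotation(spec$jitter_rotation_sd)
      shift <- stats::rnorm(3, 0, spec$jitter_translation_sd)
      M <- sweep(sweep(M, 2, cen) %*% t(U), 2, cen + shift, `+`)
      coords[t, ] <- as.numeric(t(M))
    }
  }
  trajectory_ensemble(structure, coords, frame_interval = 200)
}

# absolute pseudo-site coordinates from C-alpha geometry plus the per-frame
# pair distances: sites sit on the host-pair axis, symmetrically about its
# midpoint, at the recorded separation
build_site_coords <- function(coords, registry, planted) {
  nfr <- nrow(coords)
  S <- nrow(registry)
  out <- array(NA_real_, c(nfr, S, 3))
  for (p in seq_len(nrow(planted$pairs))) {
    i <- planted$pairs$res_i[p]
    j <- planted$pairs$res_j[p]
    d <- planted$distances[, p]
    ca_i <- residue_xyz(coords, i)
    ca_j <- residue_xyz(coords, j)
    sep <- ca_j - ca_i
    len <- sqrt(rowSums(sep^2))
    u <- sep / len
    mid <- (ca_i + ca_j) / 2
    sa <- which(registry$pair_id == p & registry$role == "acidic")
    sb <- which(registry$pair_id == p & registry$role == "basic")
    out[, sa, ] <- mid - u * (d / 2)
    out[, sb, ] <- mid + u * (d / 2)
  }
  list(registry = registry, coords = out, planted = planted)
}

#' Plant two-state salt bridges as pseudo-sites on an ensemble
#'
#' For each planted pair, an acidic and a basic pseudo-site are placed on the
#' axis between the two host C-alpha atoms; their separation in frame t is
#' `bound_distance` when a seeded Bernoulli(occupancy) draw fires, else
#' `unbound_distance`.  This keeps the occupancy statistic exactly testable
#' on C-alpha-only synthetic data.
#'
#' @param ens a `trajectory_ensemble`.
#' @param spec a `synthetic_spec` with non-NULL `planted_bridges`.
#' @return the ensemble with a `sites` component attached.
#' @export
plant_salt_bridges <- function(ens, spec) {
  pb <- spec$planted_bridges
  if (is.null(pb)) stop("spec error: no planted_bridges in spec")
  n <- n_residues(ens$structure)
  if (any(pb$res_i > n | pb$res_j > n | pb$res_i < 1 | pb$res_j < 1))
    stop("spec error: planted bridge residues outside structure")
  np <- nrow(pb)
  nfr <- n_frames(ens)
  set.seed(spec$seed + 104729L)          # bridge stream, offset from modes
  bound <- matrix(stats::runif(nfr * np) < rep(pb$occupancy, each = nfr),
                  nfr, np)
  dist <- matrix(rep(pb$unbound_distance, each = nfr), nfr, np)
  dist[bound] <- rep(pb$bound_distance, each = nfr)[bound]
  registry <- data.frame(
    site_id = seq_len(2L * np),
    global_index = as.integer(rbind(pb$res_i, pb$res_j)),
    role = rep(c("acidic", "basic"), np),
    name = rep(c("pOD", "pNZ"), np),
    pair_id = rep(seq_len(np), each = 2L),
    stringsAsFactors = FALSE)
  sites <- build_site_coords(ens$coords, registry,
                             list(pairs = pb, distances = dist))
  trajectory_ensemble(ens$structure, ens$coords, ens$frame_interval, sites)
}

#' Closed-form ground truth of a synthetic spec
#'
#' Derived deterministically from the spec with no sampling: the orthonormal
#' planted modes and eigenvalues, the per-mode and mode-subset NMSF profiles
#' (lambda_k * |v_k,i|^2, normalized per monomer), the extrema and inflection
#' residues of the subset profile found by exhaustive scan at residue
#' resolution, the planted bridge occupancies, and the sign of the mean
#' mode-filtered correlation for every domain-pair block.
#'
#' @param spec a `synthetic_spec`.
#' @param subset mode subset used for the truth profile and block signs
#'   (default the two slowest modes).
#' @param min_prominence relative prominence floor (fraction of profile
#'   range) below which scanned extrema are not reported.
#' @return object of class `planted_truth`.
#' @export
planted_truth <- function(spec, subset = NULL, min_prominence = 0.05) {
  structure <- make_toy_structure(spec)
  V <- build_mode_basis(structure, spec)
  K <- ncol(V)
  if (is.null(subset)) subset <- seq_len(min(2L, K))
  n <- n_residues(structure)
  # per-residue squared mode loadings, one column per mode
  load2 <- vapply(seq_len(K), function(k) {
    vk <- matrix(V[, k], ncol = 3, byrow = TRUE)
    rowSums(vk^2)
  }, numeric(n))
  msf_per_mode <- sweep(load2, 2, spec$eigenvalues, `*`)
  raw <- rowSums(msf_per_mode[, subset, drop = FALSE])
  mono <- structure$residues$monomer_id
  nmsf <- raw
  for (m in unique(mono)) {
    idx <- mono == m
    mx <- max(raw[idx])
    nmsf[idx] <- if (mx > 0) raw[idx] / mx else 0
  }
  extrema <- scan_extrema(nmsf, mono, min_prominence)
  inflections <- scan_inflections(nmsf, mono)
  # closed-form mode-filtered correlation sign per domain-pair block
  unit <- paste(mono, residue_domains(structure), sep = ":")
  M <- matrix(0, n, n)
  for (k in subset) {
    vk <- matrix(V[, k], ncol = 3, byrow = TRUE)
    M <- M + spec$eigenvalues[k] * tcrossprod(vk)
  }
  d <- sqrt(diag(M))
  C <- M / outer(d, d)
  units <- unique(unit)
  block_signs <- expand.grid(unit_a = units, unit_b = units,
                             stringsAsFactors = FALSE)
  block_signs$mean <- mapply(function(a, b)
    mean(C[unit == a, unit == b]), block_signs$unit_a, block_signs$unit_b)
  block_signs$sign <- ifelse(block_signs$mean > 0, "positive", "negative")
  out <- list(structure = structure,
              true_modes = V,
              true_eigenvalues = spec$eigenvalues,
              true_nmsf_per_mode = msf_per_mode,
              subset = subset,
              true_nmsf = nmsf,
              true_extrema = extrema,
              true_inflections = inflections,
              true_bridge_occupancy =
                if (is.null(spec$planted_bridges)) NULL else
                  spec$planted_bridges$occupancy,
              true_block_signs = block_signs)
  class(out) <- "planted_truth"
  out
}

# exhaustive scan for interior local extrema per monomer at residue
# resolution, with persistence pruning at a relative prominence floor
scan_extrema <- function(values, monomer, min_prominence = 0) {
  minima <- integer(0); maxima <- integer(0)
  offset <- 0L
  rng <- diff(range(values))
  for (m in unique(monomer)) {
    f <- values[monomer == m]
    ext <- extrema_of_profile(f, min_prominence * rng, margin = 0L)
    minima <- c(minima, offset + ext$minima)
    maxima <- c(maxima, offset + ext$maxima)
    offset <- offset + length(f)
  }
  list(minima = minima, maxima = maxima)
}

# exhaustive scan for curvature sign changes per monomer (discrete second
# difference), leftmost index of each crossing
scan_inflections <- function(values, monomer) {
  out <- integer(0)
  offset <- 0L
  for (m in unique(monomer)) {
    f <- values[monomer == m]
    n <- length(f)
    d2 <- f[3:n] - 2 * f[2:(n - 1)] + f[1:(n - 2)]   # curvature at 2..n-1
    s <- sign(d2)
    for (i in seq_len(length(s) - 1)) {
      if (s[i] != 0 && s[i + 1] != 0 && s[i] != s[i + 1])
        out <- c(out, offset + i + 1L)
    }
    offset <- offset + n
  }
  out
}

#' Generate the full default synthetic study ensemble
#'
#' Convenience wrapper: toy structure, planted basis, sampled trajectory and
#' (if the spec has planted bridges) pseudo-sites, in one call.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `structure`, `true_modes`, `ensemble`.
#' @export
generate_ensemble <- function(spec) {
  structure <- make_toy_structure(spec)
  V <- build_mode_basis(structure, spec)
  ens <- sample_trajectory(structure, V, spec)
  if (!is.null(spec$planted_bridges)) ens <- plant_salt_bridges(ens, spec)
  list(structure = structure, true_modes = V, ensemble = ens)
}
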