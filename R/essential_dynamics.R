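#' Cartesian covariance and residue cross-correlation of an ensemble
#'
#' Builds the 3N x 3N covariance of the centered C-alpha coordinates (the
#' time average `<dx dx^T>`, population convention) and the N x N residue
#' cross-correlation map
#' `c_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`
#' with `dr_i` the 3-vector displacement of residue i, i.e. the standard
#' dynamic cross-correlation map (DCCM) normalization of the covariance.
#'
#' @param ens a `trajectory_ensemble`, already superposed.
#' @return object of class `covariance_result`: list with `cov3N` (3N x 3N,
#'   Angstrom^2), `residue_corr` (N x N), and `undefined` (logical vector
#'   flagging zero-variance residues whose correlation rows are NA).
#' @export
covariance_matrix <- function(ens) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (n_frames(ens) < 2L) stop("need at least 2 frames for a covariance")
  X <- sweep(ens$coords, 2, colMeans(ens$coords))
  cov3N <- crossprod(X) / nrow(X)
  out <- residue_correlation_from_cov(cov3N)
  obj <- list(cov3N = cov3N, residue_corr = out$corr,
              undefined = out$undefined)
  class(obj) <- "covariance_result"
  obj
}

# N x N DCCM from a 3N x 3N covariance: numerator is the trace of each
# 3 x 3 residue block
residue_correlation_from_cov <- function(cov3N) {
  n <- nrow(cov3N) %/% 3L
  ix <- seq(1L, 3L * n, by = 3L)
  num <- cov3N[ix, ix] + cov3N[ix + 1L, ix + 1L] + cov3N[ix + 2L, ix + 2L]
  msf <- diag(num)
  undefined <- msf <= 0
  if (any(undefined))
    warning(sum(undefined), " zero-variance residue(s): correlation rows NA")
  d <- sqrt(ifelse(undefined, NA_real_, msf))
  corr <- num / outer(d, d)
  list(corr = corr, undefined = undefined)
}

#' Essential-dynamics PCA of a covariance matrix
#'
#' Full symmetric eigendecomposition of the 3N Cartesian covariance; the
#' eigenvectors are the principal (collective-motion) modes and the
#' eigenvalues their mean-square amplitudes.  Eigenvalues are sorted
#' descending, tiny negative values (numerical) clipped to zero, and each
#' eigenvector's sign fixed so its largest-magnitude component is positive.
#'
#' @param cov a `covariance_result` or a symmetric 3N x 3N matrix.
#' @return object of class `mode_set`: list with `eigenvalues` (descending,
#'   Angstrom^2), `vectors` (3N x 3N, orthonormal columns), `n_modes`.
#' @export
pca_decompose <- function(cov) {
  M <- if (inherits(cov, "covariance_result")) cov$cov3N else as.matrix(cov)
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M))))
    stop("matrix error: covariance is not symmetric")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-8 * max(vals, 0)))
    warning("covariance has significantly negative eigenvalues")
  vals[vals < 0] <- 0
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    imax <- which.max(abs(vecs[, k]))
    if (vecs[imax, k] < 0) vecs[, k] <- -vecs[, k]
  }
  obj <- list(eigenvalues = vals, vectors = vecs, n_modes = length(vals))
  class(obj) <- "mode_set"
  obj
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set:", x$n_modes, "modes; top eigenvalues (A^2):",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project an ensemble onto principal modes
#'
#' `q_k(t) = v_k . dx(t)` with dx the centered coordinates; the time series
#' of each collective-motion amplitude.
#'
#' @param ens a superposed `trajectory_ensemble`.
#' @param modes a `mode_set`.
#' @param k mode indices to project onto (default all).
#' @return T x length(k) matrix of amplitudes, one column per mode.
#' @export
project_trajectory <- function(ens, modes, k = seq_len(modes$n_modes)) {
  stopifnot(inherits(modes, "mode_set"))
  if (any(k < 1L | k > modes$n_modes))
    stop("index error: mode index out of range")
  X <- sweep(ens$coords, 2, colMeans(ens$coords))
  Q <- X %*% modes$vectors[, k, drop = FALSE]
  colnames(Q) <- paste0("q", k)
  Q
}

#' Mode-filtered residue cross-correlation map
#'
#' The cross-correlation map restricted to a subset S of modes:
#' `c_ij(S) = sum_{k in S} lambda_k (v_k,i . v_k,j) /
#'  sqrt(sum_k lambda_k |v_k,i|^2  sum_k lambda_k |v_k,j|^2)`,
#' where `v_k,i` is the 3-vector block of mode k at residue i.  This equals
#' the time correlation of the trajectory reconstructed from the subset
#' alone, so the map "computed along" one or two slow modes isolates the
#' coupling carried by those collective motions.  For a single mode the
#' eigenvalue cancels and the map is exactly the cosine of the angle between
#' the eigenvector residue blocks.
#'
#' @param modes a `mode_set`.
#' @param subset integer vector of mode indices (non-empty).
#' @return N x N correlation matrix; residues with zero subset-MSF have NA
#'   rows and an `undefined` attribute flags them.
#' @export
mode_filtered_correlation <- function(modes, subset) {
  stopifnot(inherits(modes, "mode_set"))
  if (length(subset) < 1L) stop("subset must be non-empty")
  if (any(subset < 1L | subset > modes$n_modes))
    stop("index error: mode index out of range")
  n <- nrow(modes$vectors) %/% 3L
  M <- matrix(0, n, n)
  for (k in subset) {
    vk <- matrix(modes$vectors[, k], ncol = 3, byrow = TRUE)
    M <- M + modes$eigenvalues[k] * tcrossprod(vk)
  }
  msf <- diag(M)
  undefined <- msf <= 0
  if (all(undefined))
    stop("undefined-matrix error: the mode subset carries no fluctuation")
  if (any(undefined))
    warning(sum(undefined), " residue(s) have zero subset-MSF: rows NA")
  d <- sqrt(ifelse(undefined, NA_real_, msf))
  corr <- M / outer(d, d)
  attr(corr, "undefined") <- undefined
  corr
}

#' NMSF profile over a mode subset
#'
#' Raw mean-square fluctuation of residue i restricted to the subset,
#' `MSF_i = sum_{k in S} lambda_k |v_k,i|^2`, normalized so the maximum over
#' each monomer equals 1 (the two protomers are plotted on a common axis).
#' The applied per-monomer scale is recorded.
#'
#' @param modes a `mode_set`.
#' @param subset integer vector of mode indices (non-empty).
#' @param structure the `structure_model` (for monomer/domain bookkeeping).
#' @return object of class `fluctuation_profile`: data.frame with
#'   `global_index`, `author_resid`, `monomer`, `domain`, `msf_raw`, `nmsf`;
#'   attributes `subset` and `normalization` (per-monomer max).
#' @export
nmsf_profile <- function(modes, subset, structure) {
  stopifnot(inherits(modes, "mode_set"), inherits(structure, "structure_model"))
  if (length(subset) < 1L) stop("subset must be non-empty")
  n <- n_residues(structure)
  raw <- numeric(n)
  for (k in subset) {
    vk <- matrix(modes$vectors[, k], ncol = 3, byrow = TRUE)
    raw <- raw + modes$eigenvalues[k] * rowSums(vk^2)
  }
  res <- structure$residues
  nmsf <- raw
  norm <- c()
  for (m in unique(res$monomer_id)) {
    idx <- res$monomer_id == m
    mx <- max(raw[idx])
    nmsf[idx] <- if (mx > 0) raw[idx] / mx else 0
    norm[m] <- mx
  }
  out <- data.frame(global_index = res$global_index,
                    author_resid = res$author_resid,
                    monomer = res$monomer_id,
                    domain = residue_domains(structure),
                    msf_raw = raw,
                    nmsf = nmsf,
                    stringsAsFactors = FALSE)
  class(out) <- c("fluctuation_profile", "data.frame")
  attr(out, "subset") <- subset
  attr(out, "normalization") <- norm
  out
}

#' Domain-block summary of a residue correlation map
#'
#' Averages the cross-correlation map over every ordered pair of
#' (monomer, domain) blocks, including cross-monomer blocks, and labels each
#' block positive / negative / mixed by its mean against a +-0.1 deadband.
#' This is the quantitative reading of the DCCM block structure (e.g.
#' "NTD--CTD anti-correlated, NTD--M correlated").
#'
#' @param corr N x N residue correlation matrix.
#' @param structure annotated `structure_model`; unannotated residues are
#'   excluded with a message.
#' @param deadband half-width of the mixed-sign band (default 0.1).
#' @return data.frame with `monomer_a`, `domain_a`, `monomer_b`, `domain_b`,
#'   `mean`, `min`, `max`, `n_pairs`, `sign`.
#' @export
domain_block_correlation <- function(corr, structure, deadband = 0.1) {
  stopifnot(inherits(structure, "structure_model"))
  doms <- residue_domains(structure)
  mono <- structure$residues$monomer_id
  keep <- !is.na(doms)
  if (any(!keep))
    message(sum(!keep), " unannotated residue(s) excluded from block summary")
  units <- unique(data.frame(monomer = mono[keep], domain = doms[keep],
                             stringsAsFactors = FALSE))
  rows <- list()
  for (a in seq_len(nrow(units))) for (b in seq_len(nrow(units))) {
    ia <- which(mono == units$monomer[a] & doms == units$domain[a])
    ib <- which(mono == units$monomer[b] & doms == units$domain[b])
    block <- corr[ia, ib, drop = FALSE]
    block <- block[is.finite(block)]
    if (length(block) == 0L) {
      warning("empty block ", units$monomer[a], ":", units$domain[a], " x ",
              units$monomer[b], ":", units$domain[b], " skipped")
      next
    }
    m <- mean(block)
    rows[[length(rows) + 1L]] <- data.frame(
      monomer_a = units$monomer[a], domain_a = units$domain[a],
      monomer_b = units$monomer[b], domain_b = units$domain[b],
      mean = m, min = min(block), max = max(block),
      n_pairs = length(block),
      sign = if (m > deadband) "positive"
             else if (m < -deadband) "negative" else "mixed",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Root mean square inner product between two mode subspaces
#'
#' RMSIP over the first k modes of each set: 1 for identical subspaces, 0
#' for orthogonal ones.  The standard measure of essential-subspace
#' agreement.
#'
#' @param modes_a,modes_b `mode_set` objects or 3N x >=k matrices of
#'   orthonormal columns, on the same 3N dimension.
#' @param k subspace dimension.
#' @return scalar in \[0, 1\].
#' @export
subspace_overlap <- function(modes_a, modes_b, k = 2L) {
  A <- if (inherits(modes_a, "mode_set")) modes_a$vectors else as.matrix(modes_a)
  B <- if (inherits(modes_b, "mode_set")) modes_b$vectors else as.matrix(modes_b)
  if (nrow(A) != nrow(B)) stop("dimension mismatch between mode sets")
  if (k > ncol(A) || k > ncol(B)) stop("k exceeds available modes")
  D <- crossprod(A[, seq_len(k), drop = FALSE], B[, seq_len(k), drop = FALSE])
  sqrt(sum(D^2) / k)
}
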