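#' Conformational ensemble over a C-alpha structure
#'
#' A `trajectory_ensemble` holds T frames of N C-alpha positions as a
#' T x 3N coordinate matrix (columns x1,y1,z1,x2,...), plus the frame
#' interval metadata and, optionally, named per-frame interaction sites
#' (side-chain charged atoms on real input, planted pseudo-sites on
#' synthetic input).
#'
#' @param structure a `structure_model`.
#' @param coords numeric T x 3N matrix (Angstrom).
#' @param frame_interval time between stored frames; metadata only
#'   (default 200 ps, the conventional snapshot stride).
#' @param sites optional site registry, see [plant_salt_bridges()].
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(structure, coords, frame_interval = 200,
                                sites = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  coords <- as.matrix(coords)
  n3 <- 3L * n_residues(structure)
  if (ncol(coords) != n3)
    stop("topology error: coords have ", ncol(coords),
         " columns, structure needs ", n3)
  if (nrow(coords) < 1L) stop("empty-trajectory error: no frames")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (!is.null(sites)) {
    stopifnot(is.list(sites), !is.null(sites$registry), !is.null(sites$coords))
    if (dim(sites$coords)[1] != nrow(coords))
      stop("sites must have one entry per frame")
    if (!all(sites$registry$global_index %in%
             structure$residues$global_index))
      stop("sites cover residues not in the structure")
  }
  obj <- list(structure = structure, coords = coords,
              frame_interval = frame_interval, sites = sites)
  class(obj) <- "trajectory_ensemble"
  obj
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble:", nrow(x$coords), "frames x",
      n_residues(x$structure), "residues; frame interval",
      x$frame_interval, "\n")
  if (!is.null(x$sites))
    cat("  with", nrow(x$sites$registry), "interaction sites\n")
  invisible(x)
}

n_frames <- function(ens) nrow(ens$coords)

# T x 3N -> coordinates of residue i across frames (T x 3)
residue_xyz <- function(coords, i) coords[, (3 * i - 2):(3 * i), drop = FALSE]

#' Read a C-alpha trajectory from DCD or multi-model PDB
#'
#' @param path a binary DCD trajectory or a multi-model PDB whose models are
#'   the frames.  For a DCD the atom count must equal the structure's residue
#'   count (C-alpha-only trajectory); for a PDB the C-alpha trace of each
#'   model is taken.
#' @param structure the matching `structure_model`.
#' @param frame_interval stored as metadata.
#' @return a `trajectory_ensemble`; frame order as on file.
#' @export
read_trajectory <- function(path, structure, frame_interval = 200) {
  if (!file.exists(path)) stop("file not found: ", path)
  n3 <- 3L * n_residues(structure)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
    xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
    xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
  }
  if (nrow(xyz) == 0L) stop("empty-trajectory error: ", path, " has no frames")
  if (ncol(xyz) != n3)
    stop("topology error: trajectory has ", ncol(xyz) / 3,
         " atoms per frame, structure has ", n3 / 3, " residues")
  trajectory_ensemble(structure, xyz, frame_interval)
}

#' Write a C-alpha trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision CHARMM/NAMD DCD writer (no unit cell), readable
#' by standard MD tooling.  Coordinates are truncated to float32, the native
#' precision of the format.
#'
#' @param coords T x 3N coordinate matrix or a `trajectory_ensemble`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_dcd <- function(coords, path) {
  if (inherits(coords, "trajectory_ensemble")) coords <- coords$coords
  coords <- as.matrix(coords)
  nframes <- nrow(coords)
  natom <- ncol(coords) %/% 3L
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4)
  # header record: "CORD" + 20 int32 slots (slot 10 holds the float32 delta)
  wint(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  wint(c(nframes, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  writeBin(1, con, size = 4)            # DELTA as float32
  wint(rep(0L, 9))
  wint(24L)                             # CHARMM version stamp
  wint(84)
  title <- formatC("written by modemotif::write_dcd", width = -80)
  wint(4L + 80L); wint(1L)
  writeChar(title, con, nchars = 80, eos = NULL)
  wint(4L + 80L)
  wint(4L); wint(natom); wint(4L)
  ix <- seq(1L, by = 3L, length.out = natom)
  for (t in seq_len(nframes)) {
    for (off in 0:2) {
      wint(4L * natom)
      writeBin(coords[t, ix + off], con, size = 4)
      wint(4L * natom)
    }
  }
  invisible(path)
}

#' Write a C-alpha ensemble as a multi-model PDB
#'
#' @param ens a `trajectory_ensemble`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_model_pdb <- function(ens, path) {
  res <- ens$structure$residues
  n <- nrow(res)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", t), con)
    xyz <- matrix(ens$coords[t, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(n), substr(res$resname, 1, 3), substr(res$chain, 1, 1),
      res$author_resid, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Kabsch least-squares rotation+translation of frame rows onto a reference;
# operates on plain T x 3N matrices.  fit_idx selects the residues used for
# the fit (all by default); the transform is applied to all residues.
kabsch_fit <- function(coords, ref_xyz, fit_idx = NULL) {
  natom <- ncol(coords) %/% 3L
  if (is.null(fit_idx)) fit_idx <- seq_len(natom)
  if (length(fit_idx) < 3L)
    stop("superposition error: need at least 3 residues to fit")
  R <- matrix(ref_xyz, ncol = 3, byrow = TRUE)
  Rf <- R[fit_idx, , drop = FALSE]
  if (qr(sweep(Rf, 2, colMeans(Rf)))$rank < 2L)
    stop("superposition error: degenerate (collinear) reference")
  rc <- colMeans(Rf)
  Rc <- sweep(Rf, 2, rc)
  out <- coords
  for (t in seq_len(nrow(coords))) {
    M <- matrix(coords[t, ], ncol = 3, byrow = TRUE)
    Mf <- M[fit_idx, , drop = FALSE]
    mc <- colMeans(Mf)
    A <- crossprod(sweep(Mf, 2, mc), Rc)      # 3x3 covariance of the fit set
    sv <- svd(A)
    d <- sign(det(sv$v %*% t(sv$u)))
    U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u) # proper rotation
    fitted <- sweep(sweep(M, 2, mc) %*% t(U), 2, rc, `+`)
    out[t, ] <- as.numeric(t(fitted))
  }
  out
}

#' Superpose every frame onto a reference by least squares
#'
#' Removes overall translation and rotation from each frame by a Kabsch
#' rigid-body fit onto the reference, the standard preprocessing before
#' covariance analysis.
#'
#' @param ens a `trajectory_ensemble`.
#' @param reference a frame index (default 1) or a `structure_model` with the
#'   same residue count.
#' @param fit_sel optional integer vector of residue indices used for the
#'   fit; the transform is applied to all residues.
#' @return a `trajectory_ensemble` of the same shape, superposed.  Planted
#'   pseudo-sites, which are defined relative to their host residues, are
#'   rebuilt from the fitted coordinates.
#' @export
superpose_frames <- function(ens, reference = 1L, fit_sel = NULL) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (inherits(reference, "structure_model")) {
    if (n_residues(reference) != n_residues(ens$structure))
      stop("superposition error: reference residue count differs")
    ref <- as.numeric(t(reference$calpha_coords))
  } else {
    t0 <- as.integer(reference)
    if (t0 < 1L || t0 > n_frames(ens)) stop("reference frame out of range")
    ref <- ens$coords[t0, ]
  }
  fitted <- kabsch_fit(ens$coords, ref, fit_sel)
  out <- trajectory_ensemble(ens$structure, fitted, ens$frame_interval)
  if (!is.null(ens$sites)) out$sites <- refit_sites(ens, fitted)
  out
}

# Sites ride with the rigid transform that carried their host residues.
# Planted pseudo-sites carry their per-frame pair distances and are rebuilt
# exactly from the fitted C-alpha geometry (inter-site distances are
# rigid-invariant, so occupancies are unchanged); real sites are shifted by
# their host residue's displacement.
refit_sites <- function(ens, fitted_coords) {
  sites <- ens$sites
  if (!is.null(sites$planted))
    return(build_site_coords(fitted_coords, sites$registry, sites$planted))
  reg <- sites$registry
  newc <- sites$coords
  for (s in seq_len(nrow(reg))) {
    i <- reg$global_index[s]
    old_ca <- residue_xyz(ens$coords, i)
    new_ca <- residue_xyz(fitted_coords, i)
    newc[, s, ] <- sites$coords[, s, ] + (new_ca - old_ca)
  }
  list(registry = reg, coords = newc)
}
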