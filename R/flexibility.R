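#' Per-frame RMSD versus a reference
#'
#' Each frame is least-squares superposed onto the reference and the
#' C-alpha RMSD computed, the standard monitor of trajectory drift.
#'
#' @param ens a `trajectory_ensemble`.
#' @param reference frame index (default 1) or a `structure_model`.
#' @return object of class `rmsd_series`: data.frame with `frame`, `time`
#'   and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(ens, reference = 1L) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  fitted <- superpose_frames(ens, reference)
  ref <- if (inherits(reference, "structure_model"))
    as.numeric(t(reference$calpha_coords)) else ens$coords[reference, ]
  # reference itself in its own frame of reference
  if (!inherits(reference, "structure_model"))
    ref <- fitted$coords[reference, ]
  n <- n_residues(ens$structure)
  dev <- sweep(fitted$coords, 2, ref)
  vals <- sqrt(rowSums(dev^2) / n)
  out <- data.frame(frame = seq_len(n_frames(ens)),
                    time = (seq_len(n_frames(ens)) - 1L) * ens$frame_interval,
                    rmsd = vals)
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Per-residue RMSF profile
#'
#' RMSF_i = sqrt(mean over frames of |r_i(t) - <r_i>|^2), computed about the
#' time-mean structure.  Frames are superposed onto the first frame first
#' unless `superposed = TRUE` asserts they already are.
#'
#' @param ens a `trajectory_ensemble`.
#' @param superposed set TRUE if the ensemble is already superposed; when
#'   FALSE (default) frames are fitted to frame 1 and a message records it.
#' @return object of class `rmsf_profile`: data.frame with `global_index`,
#'   `author_resid`, `monomer`, `domain`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(ens, superposed = FALSE) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (n_frames(ens) == 1L) {
    warning("single-frame ensemble: RMSF is identically zero")
    vals <- rep(0, n_residues(ens$structure))
  } else {
    if (!superposed) {
      message("superposing frames onto frame 1 before RMSF")
      ens <- superpose_frames(ens, 1L)
    }
    dev <- sweep(ens$coords, 2, colMeans(ens$coords))
    msd <- colMeans(dev^2)                       # per coordinate
    vals <- sqrt(msd[c(TRUE, FALSE, FALSE)] +
                 msd[c(FALSE, TRUE, FALSE)] +
                 msd[c(FALSE, FALSE, TRUE)])
  }
  res <- ens$structure$residues
  out <- data.frame(global_index = res$global_index,
                    author_resid = res$author_resid,
                    monomer = res$monomer_id,
                    domain = residue_domains(ens$structure),
                    rmsf = vals,
                    stringsAsFactors = FALSE)
  class(out) <- c("rmsf_profile", "data.frame")
  out
}
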