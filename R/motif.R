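#' Smooth a per-residue profile within monomers
#'
#' Centered moving average of odd window, applied per monomer so smoothing
#' never bleeds across the protomer boundary; edges use the shrinking
#' window.  Window 1 is the identity.
#'
#' @param profile a `fluctuation_profile` (or data.frame with `nmsf` and
#'   `monomer` columns).
#' @param window odd integer >= 1, <= monomer length.
#' @return the profile with `nmsf` replaced by its smoothed values (the raw
#'   values kept in `nmsf_unsmoothed`).
#' @export
smooth_profile <- function(profile, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("parameter error: window must be odd and >= 1")
  vals <- profile$nmsf
  mono <- profile$monomer
  out <- vals
  half <- window %/% 2L
  for (m in unique(mono)) {
    idx <- which(mono == m)
    if (window > length(idx))
      stop("parameter error: window exceeds monomer length")
    f <- vals[idx]
    n <- length(f)
    s <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      s[i] <- mean(f[lo:hi])
    }
    out[idx] <- s
  }
  profile$nmsf_unsmoothed <- vals
  profile$nmsf <- out
  attr(profile, "smoothing_window") <- window
  profile
}

#' Stationary points (minima and maxima) of a fluctuation profile
#'
#' Interior points of each monomer where the first difference of the
#' (smoothed) profile changes sign.  Plateaus collapse to their leftmost
#' index; extrema with prominence below `min_prominence` (a fraction of the
#' whole profile's range, making detection invariant under affine rescaling
#' of the profile) are discarded, keeping minima and maxima alternating.
#' The first and last ceiling(window/2) residues of each monomer are
#' excluded as smoothing edge artefacts.
#'
#' @param profile a (smoothed) `fluctuation_profile`.
#' @param window the smoothing window that produced the profile (sets the
#'   edge-exclusion margin); defaults to the profile's recorded window.
#' @param min_prominence relative prominence floor (default 0.05).
#' @return object of class `stationary_points`: list with integer vectors
#'   `minima`, `maxima` (global residue indices), data.frame `table` with
#'   per-point annotation and prominence, and the parameters used.
#' @export
find_stationary_points <- function(profile, window = NULL,
                                   min_prominence = 0.05) {
  if (is.null(window)) window <- attr(profile, "smoothing_window")
  if (is.null(window)) window <- 1L
  vals <- profile$nmsf
  mono <- profile$monomer
  rng <- diff(range(vals))
  margin <- as.integer(ceiling(window / 2))
  minima <- integer(0); maxima <- integer(0); prom_all <- numeric(0)
  for (m in unique(mono)) {
    idx <- which(mono == m)
    f <- vals[idx]
    n <- length(f)
    if (n < 2L * window) stop("too-short error: monomer '", m,
                              "' shorter than 2*window")
    ext <- extrema_of_profile(f, min_prominence * rng, margin)
    minima <- c(minima, idx[ext$minima])
    maxima <- c(maxima, idx[ext$maxima])
    prom_all <- c(prom_all, ext$prominence)
  }
  pts <- sort(c(minima, maxima))
  tab <- data.frame(global_index = pts,
                    author_resid = profile$author_resid[match(pts, profile$global_index)],
                    monomer = profile$monomer[match(pts, profile$global_index)],
                    domain = profile$domain[match(pts, profile$global_index)],
                    type = ifelse(pts %in% minima, "minimum", "maximum"),
                    value = vals[match(pts, profile$global_index)],
                    stringsAsFactors = FALSE)
  obj <- list(minima = minima, maxima = maxima, table = tab,
              window = window, min_prominence = min_prominence)
  class(obj) <- "stationary_points"
  obj
}


#' Inflection points of a fluctuation profile
#'
#' Interior residues of each monomer where the discrete second difference
#' (curvature) changes sign and holds the new sign for at least `min_run`
#' residues on both sides -- the turning points marking sharp
#' rigid-to-flexible transitions.  The leftmost index of each crossing is
#' reported.
#'
#' @param profile a (smoothed) `fluctuation_profile`.
#' @param window smoothing window (edge margin), as in
#'   [find_stationary_points()].
#' @param min_run minimum run length of consistent curvature sign on each
#'   side of a crossing (default 2).
#' @return integer vector of global residue indices.
#' @export
find_inflection_points <- function(profile, window = NULL, min_run = 2L) {
  min_run <- as.integer(min_run)
  if (min_run < 1L) stop("parameter error: min_run must be >= 1")
  if (is.null(window)) window <- attr(profile, "smoothing_window")
  if (is.null(window)) window <- 1L
  margin <- as.integer(ceiling(window / 2))
  vals <- profile$nmsf
  mono <- profile$monomer
  out <- integer(0)
  tol <- 1e-12 * max(abs(vals), 1)
  for (m in unique(mono)) {
    idx <- which(mono == m)
    f <- vals[idx]
    n <- length(f)
    if (n < 2L * min_run + 2L) next
    d2 <- f[3:n] - 2 * f[2:(n - 1)] + f[1:(n - 2)]   # curvature at 2..n-1
    s <- sign(d2)
    s[abs(d2) <= tol] <- 0L
    npt <- length(s)
    for (i in seq_len(npt - 1L)) {
      if (s[i] == 0) next
      # next nonzero sign after position i (zeros may sit in the crossing)
      j <- i + 1L
      while (j <= npt && s[j] == 0) j <- j + 1L
      if (j > npt || s[j] == s[i]) next
      # run checks on both sides
      left_ok <- i >= min_run && all(s[max(1, i - min_run + 1):i] == s[i])
      right_ok <- (j + min_run - 1L) <= npt &&
        all(s[j:(j + min_run - 1L)] == s[j])
      if (left_ok && right_ok) {
        res_pos <- i + 1L      # curvature index i sits at residue i+1
        if (res_pos > margin && res_pos <= n - margin)
          out <- c(out, idx[res_pos])
      }
    }
  }
  unique(out)
}

#' Cross-domain coupling partners of a residue
#'
#' Residues in a different domain or different monomer whose absolute
#' correlation with the query residue reaches the threshold, split into
#' positively and negatively coupled partners.  Residues with undefined
#' correlation are skipped.
#'
#' @param residue global residue index.
#' @param corr N x N residue correlation matrix.
#' @param structure annotated `structure_model`.
#' @param threshold absolute-correlation threshold (default 0.5, the
#'   conventional "strongly coupled" contour of DCCM maps).
#' @return list with integer vectors `positive` and `negative`.
#' @export
coupling_partners <- function(residue, corr, structure, threshold = 0.5) {
  doms <- residue_domains(structure)
  mono <- structure$residues$monomer_id
  if (is.na(doms[residue]))
    stop("residue ", residue, " is not domain-annotated")
  other <- which(mono != mono[residue] |
                 (doms != doms[residue] & !is.na(doms)))
  other <- setdiff(other, residue)
  c_row <- corr[residue, other]
  defined <- is.finite(c_row)
  hit <- other[defined & abs(c_row) >= threshold]
  vals <- c_row[defined & abs(c_row) >= threshold]
  list(positive = hit[vals > 0], negative = hit[vals < 0])
}

#' Classify stationary and inflection points into functional motifs
#'
#' Each detected point seeds a motif spanning `span_radius` residues on each
#' side, clipped at its domain boundary (so motifs never cross domains or
#' monomers).  NMSF minima become anchors (hinge-like, globally rigid),
#' maxima become recognition sites (conformationally mobile), inflections
#' become turning points.  A motif is flagged inter-domain-coupled when any
#' residue of its span has a cross-domain partner at `|c| >= threshold` in
#' the mode-filtered correlation map; motifs without support are retained
#' but flagged uncoupled.
#'
#' @param points a `stationary_points` object.
#' @param inflections integer vector from [find_inflection_points()]
#'   (optional).
#' @param corr N x N mode-filtered correlation matrix from the same mode
#'   subset as the profile.
#' @param structure annotated `structure_model`.
#' @param threshold coupling threshold on `|c|` (default 0.5).
#' @param span_radius motif half-width in residues (default 5).
#' @return object of class `functional_motifs`: data.frame with seed and
#'   span (global and author numbering), monomer, domain, class, number of
#'   positive/negative partners and `inter_domain_flag`.
#' @export
classify_motifs <- function(points, inflections = integer(0), corr,
                            structure, threshold = 0.5, span_radius = 5L) {
  stopifnot(inherits(points, "stationary_points"))
  doms <- residue_domains(structure)
  mono <- structure$residues$monomer_id
  res <- structure$residues
  seeds <- data.frame(
    seed = c(points$minima, points$maxima, inflections),
    class = c(rep("anchor", length(points$minima)),
              rep("recognition", length(points$maxima)),
              rep("turning_point", length(inflections))),
    stringsAsFactors = FALSE)
  if (nrow(seeds) == 0L) {
    out <- data.frame(seed = integer(0), class = character(0))
    class(out) <- c("functional_motifs", "data.frame")
    return(out)
  }
  seeds <- seeds[order(seeds$seed), , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(seeds))) {
    s <- seeds$seed[r]
    same_unit <- which(mono == mono[s] &
                       ((is.na(doms) & is.na(doms[s])) |
                        (!is.na(doms) & !is.na(doms[s]) & doms == doms[s])))
    lo <- max(min(same_unit), s - span_radius)
    hi <- min(max(same_unit), s + span_radius)
    span <- lo:hi
    pos <- integer(0); neg <- integer(0)
    for (q in span) {
      if (is.na(doms[q])) next
      cp <- coupling_partners(q, corr, structure, threshold)
      pos <- union(pos, cp$positive)
      neg <- union(neg, cp$negative)
    }
    rows[[r]] <- data.frame(
      seed = s, seed_author = res$author_resid[s],
      start = lo, end = hi,
      start_author = res$author_resid[lo], end_author = res$author_resid[hi],
      monomer = mono[s], domain = doms[s],
      class = seeds$class[r],
      n_positive_partners = length(pos),
      n_negative_partners = length(neg),
      inter_domain_flag = (length(pos) + length(neg)) > 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("functional_motifs", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "span_radius") <- span_radius
  out
}
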