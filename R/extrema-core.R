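# Shared 1-D extremum machinery: strict alternating extrema with
# plateau-leftmost collapse, then persistence-style pruning that removes the
# least prominent extremum (contrast against its adjacent anchors) until all
# survivors clear the floor, keeping minima/maxima alternating.  Used by the
# detector and by the synthetic-truth scanner, so "a planted extremum at
# prominence floor q" means the same thing on both sides.

# alternating interior extrema of f; plateaus collapse to leftmost index
raw_alternating_extrema <- function(f) {
  n <- length(f)
  d <- diff(f)
  s <- sign(d)
  pos <- integer(0); type <- character(0)
  last_slope <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) next
    if (last_slope != 0 && s[i] != last_slope) {
      j <- i
      while (j > 1 && s[j - 1] == 0) j <- j - 1
      pos <- c(pos, j)
      type <- c(type, if (last_slope > 0) "max" else "min")
    }
    last_slope <- s[i]
  }
  list(pos = pos, type = type)
}

# prune extrema below an absolute prominence floor; returns surviving
# (pos, type, prominence)
prune_extrema <- function(f, pos, type, min_prom_abs) {
  n <- length(f)
  repeat {
    k <- length(pos)
    if (k == 0L) break
    # anchors: adjacent extrema, monomer endpoints at the outside
    anchor_vals <- c(f[1], f[pos], f[n])
    prom <- vapply(seq_len(k), function(i)
      min(abs(f[pos[i]] - anchor_vals[i]),
          abs(f[pos[i]] - anchor_vals[i + 2L])), numeric(1))
    if (min(prom) >= min_prom_abs) return(list(pos = pos, type = type,
                                               prominence = prom))
    i <- which.min(prom)
    pos <- pos[-i]; type <- type[-i]
    # removing one extremum leaves two same-type neighbours adjacent:
    # keep the stronger
    if (i > 1L && i <= length(pos)) {
      a <- i - 1L; b <- i
      if (type[a] == type[b]) {
        drop <- if (type[a] == "max") {
          if (f[pos[a]] >= f[pos[b]]) b else a
        } else {
          if (f[pos[a]] <= f[pos[b]]) b else a
        }
        pos <- pos[-drop]; type <- type[-drop]
      }
    }
  }
  list(pos = integer(0), type = character(0), prominence = numeric(0))
}

# full pipeline on one monomer profile; margin (in residues) excludes
# reported points near the ends after pruning
extrema_of_profile <- function(f, min_prom_abs, margin = 0L) {
  raw <- raw_alternating_extrema(f)
  pr <- prune_extrema(f, raw$pos, raw$type, min_prom_abs)
  keep <- pr$pos > margin & pr$pos <= (length(f) - margin)
  list(minima = pr$pos[keep][pr$type[keep] == "min"],
       maxima = pr$pos[keep][pr$type[keep] == "max"],
       prominence = pr$prominence[keep])
}
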