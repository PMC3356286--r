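#' Charged-site registry of a structure or ensemble
#'
#' On synthetic input (a `trajectory_ensemble` carrying planted
#' pseudo-sites) the registry is the planted sites.  On real input (a bio3d
#' `pdb` object with side chains) the sites are the salt-bridge-competent
#' atoms: carboxylate oxygens of Asp (OD1/OD2) and Glu (OE1/OE2), and the
#' basic nitrogens of Lys (NZ) and Arg (NE/NH1/NH2).
#'
#' @param x a `trajectory_ensemble` with planted sites, or a bio3d `pdb`.
#' @return data.frame registry: `site_id`, `global_index`, `role`
#'   ("acidic"/"basic"), `name`; empty (with a warning) if no sites exist.
#' @export
identify_charged_sites <- function(x) {
  empty <- data.frame(site_id = integer(0), global_index = integer(0),
                      role = character(0), name = character(0),
                      stringsAsFactors = FALSE)
  if (inherits(x, "trajectory_ensemble")) {
    if (is.null(x$sites)) {
      warning("empty registry: ensemble has no interaction sites")
      return(empty)
    }
    return(x$sites$registry[, c("site_id", "global_index", "role", "name")])
  }
  if (inherits(x, "pdb")) {
    at <- x$atom[x$atom$type == "ATOM", , drop = FALSE]
    acid <- (at$resid == "ASP" & at$elety %in% c("OD1", "OD2")) |
            (at$resid == "GLU" & at$elety %in% c("OE1", "OE2"))
    base <- (at$resid == "LYS" & at$elety == "NZ") |
            (at$resid == "ARG" & at$elety %in% c("NE", "NH1", "NH2"))
    hit <- at[acid | base, , drop = FALSE]
    if (nrow(hit) == 0L) {
      warning("empty registry: no charged side-chain atoms found")
      return(empty)
    }
    # map to C-alpha residue order of the same file
    ca <- at[at$elety == "CA", , drop = FALSE]
    key <- paste(ca$chain, ca$resno)
    gidx <- match(paste(hit$chain, hit$resno), key)
    keep <- !is.na(gidx)
    data.frame(site_id = seq_len(sum(keep)),
               global_index = gidx[keep],
               role = ifelse(hit$resid[keep] %in% c("ASP", "GLU"),
                             "acidic", "basic"),
               name = hit$elety[keep],
               stringsAsFactors = FALSE)
  } else {
    stop("identify_charged_sites needs a trajectory_ensemble or bio3d pdb")
  }
}

#' Salt-bridge occupancy over an ensemble
#'
#' Every (acidic residue, basic residue) combination in the site registry is
#' a candidate pair.  A pair is formed in frame t iff the minimum distance
#' over its site pairs is at most `cutoff`; occupancy is the fraction of
#' frames formed.  Pairs never formed are dropped.  Inter-site distances are
#' rigid-invariant, so the ensemble need not be superposed.
#'
#' @param ens a `trajectory_ensemble` whose `sites` are populated.
#' @param cutoff distance criterion in Angstrom (default 4.0, the
#'   conventional N--O salt-bridge cutoff).
#' @return object of class `saltbridge_records`: data.frame with acidic and
#'   basic residue annotation (monomer, domain, author numbering, residue
#'   name), `occupancy`, `min_dist`, `mean_dist` and `class`
#'   (intra-domain / inter-domain / inter-monomer), sorted by occupancy.
#' @export
saltbridge_occupancy <- function(ens, cutoff = 4.0) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (cutoff <= 0) stop("parameter error: cutoff must be > 0")
  if (is.null(ens$sites) || nrow(ens$sites$registry) == 0L)
    stop("site registry is empty; run identify_charged_sites/plant_salt_bridges")
  reg <- ens$sites$registry
  sc <- ens$sites$coords
  nfr <- dim(sc)[1]
  res <- ens$structure$residues
  doms <- residue_domains(ens$structure)
  acid_res <- unique(reg$global_index[reg$role == "acidic"])
  base_res <- unique(reg$global_index[reg$role == "basic"])
  rows <- list()
  for (i in acid_res) for (j in base_res) {
    if (i == j) next
    si <- which(reg$role == "acidic" & reg$global_index == i)
    sj <- which(reg$role == "basic" & reg$global_index == j)
    # per-frame minimum over all site pairs of the two residues
    dmin <- rep(Inf, nfr)
    for (a in si) for (b in sj) {
      d <- sqrt(rowSums((sc[, a, , drop = TRUE] -
                         sc[, b, , drop = TRUE])^2))
      dmin <- pmin(dmin, d)
    }
    formed <- dmin <= cutoff
    if (!any(formed)) next
    cls <- if (res$monomer_id[i] != res$monomer_id[j]) "inter-monomer"
           else if (!identical(doms[i], doms[j]) &&
                    !(is.na(doms[i]) && is.na(doms[j]))) "inter-domain"
           else "intra-domain"
    rows[[length(rows) + 1L]] <- data.frame(
      acidic_index = i, acidic_resid = res$author_resid[i],
      acidic_resname = res$resname[i], acidic_monomer = res$monomer_id[i],
      acidic_domain = doms[i],
      basic_index = j, basic_resid = res$author_resid[j],
      basic_resname = res$resname[j], basic_monomer = res$monomer_id[j],
      basic_domain = doms[j],
      occupancy = mean(formed),
      min_dist = min(dmin), mean_dist = mean(dmin),
      class = cls, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(occupancy = numeric(0))
  if (nrow(out) > 0) out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("saltbridge_records", "data.frame")
  attr(out, "cutoff") <- cutoff
  out
}

#' Filter salt-bridge records by minimum occupancy
#'
#' @param records a `saltbridge_records` data.frame.
#' @param min_occ occupancy threshold; the conventional tiers are 0.90
#'   ("high occupancy") and 0.95 ("most stabilizing").  Values above 1
#'   yield an empty set.
#' @return the records with `occupancy >= min_occ`, sorted descending.
#' @export
filter_by_occupancy <- function(records, min_occ = 0.90) {
  if (min_occ < 0) stop("min_occ must be non-negative")
  out <- records[records$occupancy >= min_occ, , drop = FALSE]
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count salt bridges per domain and class
#'
#' Each record is attributed to its acidic residue's domain (with an
#' interface label when the two domains differ) and tallied per domain and
#' per class (intra-domain / inter-domain / inter-monomer), the domain-based
#' distribution of high-occupancy bridges.
#'
#' @param records a `saltbridge_records` data.frame.
#' @return list with `by_domain` and `by_class` count tables and the
#'   per-record `labels` (interface label, e.g. "M-CTD", or the domain).
#' @export
classify_domain_pairs <- function(records) {
  if (nrow(records) == 0L)
    return(list(by_domain = table(character(0)),
                by_class = table(character(0)), labels = character(0)))
  da <- records$acidic_domain
  db <- records$basic_domain
  unassigned <- is.na(da)
  if (any(unassigned))
    message(sum(unassigned), " record(s) with unannotated acidic residue ",
            "counted as 'unassigned'")
  da[is.na(da)] <- "unassigned"
  db[is.na(db)] <- "unassigned"
  labels <- ifelse(da == db, da, paste(da, db, sep = "-"))
  list(by_domain = table(domain = da),
       by_class = table(class = records$class),
       labels = labels)
}

#' Per-pair formation time traces
#'
#' Distance and formed-flag versus frame for each retained pair, the
#' time-dependent history of the bridges.
#'
#' @param ens a `trajectory_ensemble` with sites.
#' @param records output of [saltbridge_occupancy()] (uses its cutoff).
#' @return data.frame with `pair`, `frame`, `time`, `distance`, `formed`.
#' @export
saltbridge_traces <- function(ens, records) {
  reg <- ens$sites$registry
  sc <- ens$sites$coords
  cutoff <- attr(records, "cutoff")
  nfr <- dim(sc)[1]
  out <- list()
  for (r in seq_len(nrow(records))) {
    si <- which(reg$role == "acidic" &
                reg$global_index == records$acidic_index[r])
    sj <- which(reg$role == "basic" &
                reg$global_index == records$basic_index[r])
    dmin <- rep(Inf, nfr)
    for (a in si) for (b in sj)
      dmin <- pmin(dmin, sqrt(rowSums((sc[, a, , drop = TRUE] -
                                       sc[, b, , drop = TRUE])^2)))
    out[[r]] <- data.frame(
      pair = paste0(records$acidic_resname[r], records$acidic_resid[r], "-",
                    records$basic_resname[r], records$basic_resid[r]),
      frame = seq_len(nfr),
      time = (seq_len(nfr) - 1L) * ens$frame_interval,
      distance = dmin,
      formed = dmin <= cutoff,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
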