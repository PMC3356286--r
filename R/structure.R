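#' Reference C-alpha structure with monomer/domain annotation
#'
#' A `structure_model` holds an ordered C-alpha residue table, the reference
#' coordinates, and a domain map assigning author-numbered residue ranges to
#' (monomer, domain) labels, e.g. the three-domain architecture of an Hsp90
#' protomer (NTD / M-domain / CTD).
#'
#' @param residues data.frame with columns `global_index` (contiguous 1..N in
#'   file order), `monomer_id`, `author_resid`, `resname`, `chain`.
#' @param calpha_coords numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param domain_map data.frame with columns `monomer_id`, `domain`,
#'   `author_start`, `author_end`, or NULL for an unannotated model.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(residues, calpha_coords, domain_map = NULL) {
  residues <- as.data.frame(residues)
  stopifnot(all(c("global_index", "monomer_id", "author_resid",
                  "resname", "chain") %in% names(residues)))
  n <- nrow(residues)
  if (n < 2L)
    stop("empty-model error: a structure model needs at least 2 residues")
  if (!identical(residues$global_index, seq_len(n)))
    stop("global_index must be contiguous 1..N in file order")
  calpha_coords <- as.matrix(calpha_coords)
  if (!is.numeric(calpha_coords) || nrow(calpha_coords) != n ||
      ncol(calpha_coords) != 3L)
    stop("calpha_coords must be a numeric N x 3 matrix")
  if (!all(is.finite(calpha_coords)))
    stop("calpha_coords must be finite")
  if (!is.null(domain_map)) {
    domain_map <- as.data.frame(domain_map)
    stopifnot(all(c("monomer_id", "domain", "author_start", "author_end")
                  %in% names(domain_map)))
    for (m in unique(domain_map$monomer_id)) {
      dm <- domain_map[domain_map$monomer_id == m, , drop = FALSE]
      if (nrow(dm) > 1L) {
        o <- order(dm$author_start)
        if (any(dm$author_end[o][-nrow(dm)] >= dm$author_start[o][-1L]))
          stop("domain ranges within monomer '", m, "' overlap")
      }
    }
  }
  obj <- list(residues = residues, calpha_coords = calpha_coords,
              domain_map = domain_map)
  class(obj) <- "structure_model"
  obj
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$residues), "residues,",
      length(unique(x$residues$monomer_id)), "monomer(s)\n")
  if (!is.null(x$domain_map)) {
    cat("domain map:\n")
    print(x$domain_map, row.names = FALSE)
  }
  invisible(x)
}

n_residues <- function(structure) nrow(structure$residues)

#' Domain label per residue
#'
#' Maps each residue of a structure to its domain label from the domain map.
#' Residues outside every annotated range get NA.
#'
#' @param structure a `structure_model`.
#' @return character vector length N of domain labels (NA if unannotated).
#' @export
residue_domains <- function(structure) {
  res <- structure$residues
  out <- rep(NA_character_, nrow(res))
  dm <- structure$domain_map
  if (is.null(dm)) return(out)
  for (k in seq_len(nrow(dm))) {
    hit <- res$monomer_id == dm$monomer_id[k] &
      res$author_resid >= dm$author_start[k] &
      res$author_resid <= dm$author_end[k]
    out[hit] <- dm$domain[k]
  }
  out
}

#' Read a reference C-alpha structure from a PDB file
#'
#' Extracts the C-alpha trace of the first model, preserving file order and
#' author residue numbering.  Residues without a C-alpha atom are dropped with
#' a warning.  Monomers are identified by chain ID unless `monomer_ids` is
#' given.
#'
#' @param path PDB file.
#' @param domain_map optional data.frame (`monomer_id`, `domain`,
#'   `author_start`, `author_end`) in author numbering.
#' @param monomer_ids optional character vector length N overriding the
#'   chain-based monomer assignment.
#' @return a `structure_model`.
#' @export
read_structure <- function(path, domain_map = NULL, monomer_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("format error reading '", path,
                                           "': ", conditionMessage(e)))
  ca <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$type == "ATOM", ,
                 drop = FALSE]
  if (nrow(ca) == 0L) stop("empty-model error: no C-alpha atoms in ", path)
  # residues present in the file but lacking a CA are dropped
  prot <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  key_all <- unique(paste(prot$chain, prot$resno))
  key_ca <- paste(ca$chain, ca$resno)
  missing_ca <- setdiff(key_all, key_ca)
  if (length(missing_ca) > 0L)
    warning(length(missing_ca), " residue(s) lack a C-alpha atom and were dropped")
  if (nrow(ca) < 2L) stop("empty-model error: fewer than 2 C-alpha residues")
  chain <- ifelse(is.na(ca$chain), "A", ca$chain)
  residues <- data.frame(
    global_index = seq_len(nrow(ca)),
    monomer_id = if (is.null(monomer_ids)) chain else monomer_ids,
    author_resid = ca$resno,
    resname = ca$resid,
    chain = chain,
    stringsAsFactors = FALSE)
  structure_model(residues, cbind(ca$x, ca$y, ca$z), domain_map)
}

#' Write a per-residue scalar map into PDB B-factors
#'
#' Writes the C-alpha trace with each residue's value in the B-factor column,
#' the standard vehicle for residue-level flexibility maps.  Values are
#' affinely mapped into the printable B-factor range \[0, 999.99\] only when
#' they fall outside it; the applied transform is recorded as the
#' `bfactor_transform` attribute and reported via `message()`.
#'
#' @param structure a `structure_model`.
#' @param values numeric vector length N, finite.
#' @param path output PDB path.
#' @return (invisibly) the transformed values actually written.
#' @export
write_bfactor_pdb <- function(structure, values, path) {
  n <- n_residues(structure)
  if (length(values) != n)
    stop("dimension error: expected ", n, " values, got ", length(values))
  if (!all(is.finite(values))) stop("values must be finite")
  shift <- 0; scale <- 1
  lo <- min(values); hi <- max(values)
  if (lo < 0) shift <- -lo
  if ((hi + shift) > 999.99) scale <- 999.99 / (hi + shift)
  out <- (values + shift) * scale
  if (shift != 0 || scale != 1)
    message("B-factor affine transform applied: (x + ", signif(shift, 6),
            ") * ", signif(scale, 6))
  res <- structure$residues
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(structure$calpha_coords)),
    resno = res$author_resid,
    resid = res$resname,
    chain = res$chain,
    elety = rep("CA", n),
    b = round(out, 2))
  attr(out, "bfactor_transform") <- c(shift = shift, scale = scale)
  invisible(out)
}
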