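#' Pipeline configuration
#'
#' Builds and validates the single source of truth for a pipeline run:
#' either a synthetic-ensemble spec or real input paths (reference PDB +
#' DCD/multi-model-PDB trajectory with a domain map), plus all stage
#' parameters.  Exactly one input route must be present.
#'
#' @param synthetic list of [synthetic_spec()] arguments, or a
#'   `synthetic_spec`, or NULL.
#' @param input list with `structure` (PDB path), `trajectory` (DCD or
#'   multi-model PDB path) and `domain_map` (data.frame or list of rows with
#'   monomer_id/domain/author_start/author_end), or NULL.
#' @param params named list overriding stage parameter defaults:
#'   `cutoff` (salt-bridge distance, A), `min_occupancy`, `modes` (slow-mode
#'   subset), `window` (smoothing), `min_prominence`, `min_run`,
#'   `corr_threshold`, `span_radius`, `superpose_reference`.
#' @param seed integer seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            params = list(), seed = 42L) {
  if (is.null(synthetic) == is.null(input))
    stop("config error: exactly one of synthetic spec or real input required")
  defaults <- list(cutoff = 4.0, min_occupancy = 0.90, modes = c(1L, 2L),
                   window = 5L, min_prominence = 0.05, min_run = 2L,
                   corr_threshold = 0.5, span_radius = 5L,
                   superpose_reference = 1L)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0)
    stop("config error: unknown parameter(s) ",
         paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  if (defaults$cutoff <= 0 || defaults$min_occupancy < 0 ||
      defaults$min_occupancy > 1 || defaults$window %% 2L == 0L)
    stop("config error: parameter out of documented range")
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_spec")) {
    synthetic$seed <- if (!is.null(synthetic$seed)) synthetic$seed else seed
    synthetic <- do.call(synthetic_spec, synthetic)
  }
  if (!is.null(input)) {
    stopifnot(!is.null(input$structure), !is.null(input$trajectory))
    if (!is.null(input$domain_map) && !is.data.frame(input$domain_map))
      input$domain_map <- do.call(rbind, lapply(input$domain_map,
                                                as.data.frame))
  }
  obj <- list(synthetic = synthetic, input = input, params = defaults,
              seed = as.integer(seed))
  class(obj) <- "pipeline_config"
  obj
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `synthetic` or
#' `input`, `params`, `seed`.  A `planted_bridges` list under `synthetic`
#' is converted to the bridge data.frame.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    if (!is.null(y$synthetic$planted_bridges))
      y$synthetic$planted_bridges <-
        do.call(rbind, lapply(y$synthetic$planted_bridges, as.data.frame))
    if (!is.null(y$synthetic$domain_fractions))
      y$synthetic$domain_fractions <- unlist(y$synthetic$domain_fractions)
    if (!is.null(y$synthetic$eigenvalues))
      y$synthetic$eigenvalues <- unlist(y$synthetic$eigenvalues)
    if (!is.null(y$synthetic$mode_shapes))
      y$synthetic$mode_shapes <- lapply(y$synthetic$mode_shapes, function(s) {
        s$domain_weights <- unlist(s$domain_weights)
        s$monomer_signs <- unlist(s$monomer_signs)
        do.call(mode_shape, s)
      })
  }
  if (!is.null(y$params$modes)) y$params$modes <- as.integer(unlist(y$params$modes))
  pipeline_config(synthetic = y$synthetic, input = y$input,
                  params = if (is.null(y$params)) list() else y$params,
                  seed = if (is.null(y$seed)) 42L else y$seed)
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full trajectory-analysis pipeline
#'
#' Executes superposition, RMSD/RMSF profiling, salt-bridge occupancy
#' analysis, essential-dynamics PCA, mode-filtered cross-correlation and
#' NMSF profiling, and motif calling, writing all tables plus a
#' machine-readable report.  With a fixed config and seed the report JSON is
#' byte-identical across runs; wall-clock metadata is isolated in the
#' manifest.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed); NULL to skip all
#'   file output and just return the bundle.
#' @return (invisibly) list with every stage result and `report` (the list
#'   serialized to report.json).
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  t_start <- Sys.time()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- input -----------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    gen <- stage("simulate", generate_ensemble(config$synthetic))
    structure <- gen$structure
    ens <- gen$ensemble
    truth <- planted_truth(config$synthetic, subset = p$modes,
                           min_prominence = p$min_prominence)
  } else {
    structure <- stage("read_structure",
                       read_structure(config$input$structure,
                                      domain_map = config$input$domain_map))
    ens <- stage("read_trajectory",
                 read_trajectory(config$input$trajectory, structure))
  }

  # --- flexibility -----------------------------------------------------
  fitted <- stage("superpose", superpose_frames(ens, p$superpose_reference))
  rmsd <- stage("rmsd", rmsd_series(ens, p$superpose_reference))
  rmsf <- stage("rmsf", rmsf_profile(fitted, superposed = TRUE))

  # --- salt bridges ----------------------------------------------------
  bridges <- NULL; bridge_counts <- NULL; high_occ <- NULL
  if (!is.null(ens$sites)) {
    bridges <- stage("bridges", saltbridge_occupancy(ens, p$cutoff))
    high_occ <- filter_by_occupancy(bridges, p$min_occupancy)
    bridge_counts <- classify_domain_pairs(high_occ)
  }

  # --- essential dynamics ----------------------------------------------
  cov <- stage("covariance", covariance_matrix(fitted))
  modes <- stage("pca", pca_decompose(cov))
  corr_S <- stage("mode_correlation",
                  mode_filtered_correlation(modes, p$modes))
  nmsf <- stage("nmsf", nmsf_profile(modes, p$modes, structure))
  blocks <- stage("blocks", domain_block_correlation(corr_S, structure))

  # --- motifs ----------------------------------------------------------
  smoothed <- stage("smooth", smooth_profile(nmsf, p$window))
  pts <- stage("stationary",
               find_stationary_points(smoothed, p$window, p$min_prominence))
  infl <- stage("inflections",
                find_inflection_points(smoothed, p$window, p$min_run))
  motifs <- stage("motifs",
                  classify_motifs(pts, infl, corr_S, structure,
                                  p$corr_threshold, p$span_radius))

  report <- list(
    n_residues = n_residues(structure),
    n_frames = n_frames(ens),
    seed = config$seed,
    parameters = p,
    rmsd_mean = mean(rmsd$rmsd),
    rmsd_final = rmsd$rmsd[nrow(rmsd)],
    rmsf_by_domain = stats::aggregate(rmsf ~ monomer + domain, rmsf, mean),
    eigenvalues_top = utils::head(modes$eigenvalues, 10),
    variance_captured = sum(modes$eigenvalues[p$modes]) /
      sum(modes$eigenvalues),
    block_summary = blocks,
    n_bridges = if (is.null(bridges)) 0L else nrow(bridges),
    n_high_occupancy = if (is.null(high_occ)) 0L else nrow(high_occ),
    bridge_counts_by_domain = if (is.null(bridge_counts)) NULL else
      as.list(bridge_counts$by_domain),
    motifs = motifs,
    n_anchor = sum(motifs$class == "anchor"),
    n_recognition = sum(motifs$class == "recognition"),
    n_turning_point = sum(motifs$class == "turning_point"))

  bundle <- list(structure = structure, ensemble = ens, fitted = fitted,
                 rmsd = rmsd, rmsf = rmsf, bridges = bridges,
                 high_occupancy = high_occ, covariance = cov, modes = modes,
                 mode_correlation = corr_S, nmsf = nmsf, smoothed = smoothed,
                 stationary = pts, inflections = infl, blocks = blocks,
                 motifs = motifs, truth = truth, report = report)

  if (!is.null(out_dir)) {
    write_tsv(rmsd, file.path(out_dir, "rmsd.tsv"))
    write_tsv(rmsf, file.path(out_dir, "rmsf.tsv"))
    if (!is.null(bridges)) {
      write_tsv(bridges, file.path(out_dir, "saltbridges.tsv"))
      write_tsv(saltbridge_traces(ens, bridges),
                file.path(out_dir, "saltbridge_traces.tsv"))
    }
    write_tsv(as.data.frame(corr_S), file.path(out_dir, "dccm.tsv"))
    write_tsv(blocks, file.path(out_dir, "block_summary.tsv"))
    write_tsv(nmsf, file.path(out_dir, "nmsf.tsv"))
    write_tsv(motifs, file.path(out_dir, "motifs.tsv"))
    jsonlite::write_json(
      list(eigenvalues = modes$eigenvalues),
      file.path(out_dir, "eigen_spectrum.json"), digits = NA)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    write_bfactor_pdb(structure, rmsf$rmsf,
                      file.path(out_dir, "rmsf_bfactor.pdb"))
    motif_mask <- as.numeric(structure$residues$global_index %in%
                               unlist(mapply(seq, motifs$start, motifs$end,
                                             SIMPLIFY = FALSE)))
    write_bfactor_pdb(structure, motif_mask,
                      file.path(out_dir, "motif_membership.pdb"))
    manifest <- list(package = "modemotif",
                     version = as.character(utils::packageVersion("modemotif")),
                     timestamp = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
                     elapsed_sec = as.numeric(difftime(Sys.time(), t_start,
                                                       units = "secs")),
                     seed = config$seed,
                     parameters = p,
                     synthetic = !is.null(config$synthetic))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(bundle)
}
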