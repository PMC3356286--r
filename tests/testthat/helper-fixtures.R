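# shared fixtures, all built in code

# small annotated structure: n residues per monomer, chains A/B, author
# numbering restarting per monomer, thirds as NTD/M/CTD
tiny_structure <- function(n_per = 10L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per
  coords <- matrix(rnorm(3 * n, sd = 5), n, 3)
  thirds <- round(n_per * c(1, 2, 3) / 3)
  residues <- data.frame(global_index = seq_len(n),
                         monomer_id = rep(c("A", "B"), each = n_per),
                         author_resid = rep(seq_len(n_per), 2),
                         resname = "ALA",
                         chain = rep(c("A", "B"), each = n_per),
                         stringsAsFactors = FALSE)
  dm <- data.frame(monomer_id = rep(c("A", "B"), each = 3),
                   domain = rep(c("NTD", "M", "CTD"), 2),
                   author_start = rep(c(1, thirds[1] + 1, thirds[2] + 1), 2),
                   author_end = rep(thirds, 2),
                   stringsAsFactors = FALSE)
  structure_model(residues, coords, dm)
}

# random ensemble over a structure (frames = reference + noise)
hand_ensemble <- function(structure, n_frames, sd = 1, seed = 2L) {
  set.seed(seed)
  n3 <- 3L * nrow(structure$residues)
  ref <- as.numeric(t(structure$calpha_coords))
  coords <- sweep(matrix(rnorm(n_frames * n3, sd = sd), n_frames, n3),
                  2, ref, `+`)
  trajectory_ensemble(structure, coords)
}

# wrap an explicit eigen-system as a mode_set
as_mode_set <- function(vectors, eigenvalues) {
  structure(list(eigenvalues = eigenvalues, vectors = as.matrix(vectors),
                 n_modes = length(eigenvalues)),
            class = "mode_set")
}

# bare fluctuation-profile data.frame for one or two monomers
profile_df <- function(values, n_per = length(values)) {
  n <- length(values)
  data.frame(global_index = seq_len(n),
             author_resid = rep(seq_len(n_per), length.out = n),
             monomer = rep(LETTERS[seq_len(ceiling(n / n_per))],
                           each = n_per)[seq_len(n)],
             domain = "M",
             nmsf = values,
             stringsAsFactors = FALSE)
}

# apply one rigid transform (rotation + translation) to every frame
rigid_transform_ensemble <- function(ens, angle = 0.7, axis = c(0, 0, 1),
                                     shift = c(5, -3, 2)) {
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  U <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  coords <- ens$coords
  for (t in seq_len(nrow(coords))) {
    M <- matrix(coords[t, ], ncol = 3, byrow = TRUE)
    coords[t, ] <- as.numeric(t(M %*% t(U) + rep(1, nrow(M)) %o% shift))
  }
  trajectory_ensemble(ens$structure, coords, ens$frame_interval, ens$sites)
}

# default spec with planted bridges, used across test files
bridged_spec <- function(seed = 42L, n_frames = 1000L,
                         occupancy = c(0.99, 0.93, 0.42)) {
  synthetic_spec(n_frames = n_frames, seed = seed,
                 planted_bridges = data.frame(
                   res_i = c(10L, 50L, 70L), res_j = c(30L, 90L, 110L),
                   occupancy = occupancy))
}
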