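#!/usr/bin/env Rscript
# Stage 4: essential-dynamics PCA, slow-mode cross-correlation map, NMSF
# profiles and domain-block coupling summary.
#
# The covariance of the superposed C-alpha ensemble is diagonalized; the
# cross-correlation map and the NMSF profile are then restricted to the two
# slowest modes, and block means quantify the inter-domain coupling signs.

suppressMessages(library(modemotif))
src <- "results/synthetic"
if (!file.exists(file.path(src, "trajectory.dcd")))
  stop("run analysis/01_simulate.R first")
out <- "results/essential_dynamics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dm <- read.table(file.path(src, "domain_map.tsv"), header = TRUE, sep = "\t")
st <- read_structure(file.path(src, "reference.pdb"), domain_map = dm)
ens <- read_trajectory(file.path(src, "trajectory.dcd"), st)
fit <- superpose_frames(ens, 1L)

cv <- covariance_matrix(fit)
md <- pca_decompose(cv)
cc <- mode_filtered_correlation(md, 1:2)
nmsf <- nmsf_profile(md, 1:2, st)
blocks <- domain_block_correlation(cc, st)

write.table(round(cc, 6), file.path(out, "dccm_slow2.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(nmsf, file.path(out, "nmsf.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(blocks, file.path(out, "block_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(eigenvalues = md$eigenvalues),
                     file.path(out, "eigen_spectrum.json"), digits = NA)

top <- md$eigenvalues[1:5]
message("top eigenvalues (A^2): ", paste(signif(top, 4), collapse = ", "))
message(sprintf("two slowest modes carry %.0f%% of the total fluctuation",
                100 * sum(md$eigenvalues[1:2]) / sum(md$eigenvalues)))
for (r in which(blocks$monomer_a == "A" & blocks$monomer_b == "A" &
                blocks$domain_a == "NTD" & blocks$domain_b != "NTD"))
  message(sprintf("  NTD-%s block mean correlation %+0.2f (%s)",
                  blocks$domain_b[r], blocks$mean[r], blocks$sign[r]))
message("the NTD moves with the M-domain and against the CTD -- the ",
        "anti-correlated inter-domain architecture planted in mode 1")
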