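#!/usr/bin/env Rscript
# Stage 2: RMSD time series and per-residue RMSF profile.
#
# Reads the stage-1 reference PDB + DCD back from disk (exercising the
# trajectory reader), superposes all frames onto frame 1, and profiles the
# flexibility per residue and per domain.

suppressMessages(library(modemotif))
src <- "results/synthetic"
if (!file.exists(file.path(src, "trajectory.dcd")))
  stop("run analysis/01_simulate.R first")
out <- "results/flexibility"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dm <- read.table(file.path(src, "domain_map.tsv"), header = TRUE, sep = "\t")
st <- read_structure(file.path(src, "reference.pdb"), domain_map = dm)
ens <- read_trajectory(file.path(src, "trajectory.dcd"), st)

rmsd <- rmsd_series(ens, reference = 1L)
fit <- superpose_frames(ens, 1L)
rmsf <- rmsf_profile(fit, superposed = TRUE)

write.table(rmsd, file.path(out, "rmsd.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rmsf, file.path(out, "rmsf.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write_bfactor_pdb(st, rmsf$rmsf, file.path(out, "rmsf_bfactor.pdb"))

message(sprintf("RMSD: mean %.2f A, final %.2f A over %d frames",
                mean(rmsd$rmsd), rmsd$rmsd[nrow(rmsd)], nrow(rmsd)))
agg <- aggregate(rmsf ~ monomer + domain, rmsf, mean)
message("mean RMSF by domain (A):")
for (r in seq_len(nrow(agg)))
  message(sprintf("  %s:%s  %.2f", agg$monomer[r], agg$domain[r], agg$rmsf[r]))
message("NTD fluctuates most, the M-domain least -- the planted mode 1 ",
        "loads its largest amplitudes on the terminal domains")
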