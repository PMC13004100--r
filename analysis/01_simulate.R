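#!/usr/bin/env Rscript
# Generate the synthetic study data: bead-model conformer trajectories for
# the WT and VARIANT models from circular and linear starts, and two-trait
# GWAS summary statistics with a shared causal variant.  Writes example
# inputs under results/data/ so every later step can also be rerun from
# files.

suppressPackageStartupMessages(library(conformgen))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

sc <- calibrate_scenario(conformer_scenario())
cat(sprintf("scenario: %d residues, %d frames x %d repeats per (model, start)\n",
            sc$n_residues, sc$n_frames, sc$n_repeats))
cat(sprintf("planted burial %.0f%% (side-bead tuck %.3f), exposure +%.0f%% (push %.2f A)\n",
            100 * sc$burial_fraction, sc$calibration$tuck,
            100 * sc$exposure_fraction, sc$calibration$push))

# one example trajectory per (model, start shape), written as multi-model PDB
truth_rows <- list()
k <- 0L
for (model in c("WT", "VARIANT")) for (shape in c("circular", "linear")) {
  k <- k + 1L
  sim <- simulate_conformer_trajectory(sc, model, shape, repeat_id = 1L,
                                       seed = seed + k)
  path <- file.path(out, sprintf("traj_%s_%s_rep1.pdb", model, shape))
  write_multi_model_pdb(sim$trajectory, path)
  truth_rows[[k]] <- data.frame(model_label = model, start_shape = shape,
                                frame = seq_along(sim$truth$state),
                                state = sim$truth$state)
  cat("wrote", path, "-", n_frames(sim$trajectory), "frames\n")
}
write.table(do.call(rbind, truth_rows), file.path(out, "trajectory_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# per-residue planted exposure classes
cls <- rep("neutral", sc$n_residues)
cls[sc$buried_loop] <- "buried_in_variant"
cls[sc$exposed_motif] <- "exposed_in_variant"
write.table(data.frame(residue_index = seq_len(sc$n_residues),
                       exposure_class = cls),
            file.path(out, "residue_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# two-trait GWAS summary statistics, shared causal variant
gw <- simulate_two_trait_summary_stats(seed = seed)
write.table(gw$trait1, file.path(out, "trait1_sumstats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(gw$trait2, file.path(out, "trait2_sumstats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("GWAS scenario: %d variants, shared causal at index %d (beta %.3f)\n",
            nrow(gw$trait1), gw$truth$causal_index1, gw$truth$true_beta1))
cat("done\n")
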