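#!/usr/bin/env Rscript
# Rigid-body Metropolis Monte Carlo mapping of the two ring ligands in the
# receptor field: 400 independent runs of 25000 steps at 300 K within a
# 100 A centre-of-mass ball. Reports the patch-hemisphere pose-density
# enrichment and the top-pose energy contrast between the negative-ring
# (competent partner analogue) and positive-ring (incompetent) ligand.
# Full pose tables go to scratch/; a thinned table and the summary to
# results/.

suppressPackageStartupMessages(library(redoxmap))
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

rec <- make_patch_receptor(seed = 1)
lig_neg <- make_ring_ligand(ring_charge = -0.5, seed = 2)
lig_pos <- make_ring_ligand(ring_charge = +0.5, seed = 2)
I <- ionic_strength(phosphate_buffer(0.02, 7, 7.2))
grid <- compute_potential_grid(rec, spacing = 2,
                               origin = c(-110, -110, -110),
                               dims = c(111, 111, 111), ionic_strength = I)
cfg <- mc_config(n_runs = 400, n_steps = 25000, d_max = 100, seed = 7)
axis <- attr(rec, "patch_axis")

run_one <- function(lig, label) {
  t0 <- Sys.time()
  ens <- run_mapping(rec, lig, grid, cfg)
  cat(sprintf("%s: %d poses in %.1f s, acceptance %.2f\n", label,
              nrow(ens$poses), as.numeric(Sys.time() - t0, units = "secs"),
              mean(ens$acceptance)))
  write.table(format(ens$poses, digits = 10),
              sprintf("scratch/poses_%s.tsv", label),
              sep = "\t", row.names = FALSE, quote = FALSE)
  ens
}

ens_neg <- run_one(lig_neg, "negative_ring")
ens_pos <- run_one(lig_pos, "positive_ring")

top_neg <- select_top_poses(ens_neg, "lowest_energy", 0.1)
top_pos <- select_top_poses(ens_pos, "lowest_energy", 0.1)
summary_tab <- data.frame(
  ligand = c("negative_ring", "positive_ring"),
  n_poses = c(nrow(ens_neg$poses), nrow(ens_pos$poses)),
  acceptance = c(mean(ens_neg$acceptance), mean(ens_pos$acceptance)),
  patch_enrichment = c(hemisphere_enrichment(ens_neg, axis),
                       hemisphere_enrichment(ens_pos, axis)),
  mean_top_energy_kBT = c(mean(top_neg$poses$energy),
                          mean(top_pos$poses$energy)),
  min_energy_kBT = c(min(ens_neg$poses$energy), min(ens_pos$poses$energy)))
write.table(summary_tab, "results/mapping_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
# a thinned pose table small enough to keep under results/
thin <- ens_neg$poses[seq(1, nrow(ens_neg$poses), by = 100), ]
write.table(format(thin, digits = 8), "results/poses_negative_ring_thinned.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

print(summary_tab, digits = 4)
cat(sprintf("\npatch-hemisphere enrichment: %.1f-fold (negative ring) vs %.2f (positive ring)\n",
            summary_tab$patch_enrichment[1], summary_tab$patch_enrichment[2]))
cat("only the ligand whose ring charge complements the patch accumulates there;\n")
cat("its geometry-identical sign mirror samples the ball almost uniformly\n")
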