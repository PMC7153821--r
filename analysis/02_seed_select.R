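#!/usr/bin/env Rscript
# Stage 2 — seed selection by cutoff clustering.
#
# Emulates turning one long exploratory trajectory into short-run seeds:
# frames of a single trajectory are clustered by unweighted average linkage
# under a dihedral-metric distance cutoff of 0.3 (the torsion-space analogue
# of the Cartesian cutoff criterion), and each cluster contributes its
# medoid as a seed structure.

suppressPackageStartupMessages(library(loopmsm))
dir.create("results", showWarnings = FALSE)

spec <- default_synthetic_spec(seed = 1, n_traj = 1, traj_len = 400)
traj <- generate_torsion_ensemble(spec)$trajectories[[1]]

D <- pairwise_distances(traj, metric = "dihedral")
res <- average_linkage_cluster(D, cutoff = 0.3)
res <- pick_representatives(res, D)

utils::write.csv(
  data.frame(cluster = seq_len(res$n_clusters),
             size = res$sizes,
             representative_frame = res$representatives),
  "results/seeds.csv", row.names = FALSE)

cat(sprintf("clustered %d frames at dihedral cutoff %.2f -> %d clusters\n",
            nrow(traj$angles), res$cutoff, res$n_clusters))
cat(sprintf("largest cluster: %d frames; %d singletons\n",
            max(res$sizes), sum(res$sizes == 1)))
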