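#!/usr/bin/env Rscript
# Generate the synthetic study systems: a wild-type reference ensemble and
# four modified variants (S/R isomer pairs) whose two leading collective
# motions are respectively identical, swapped, rotated by 45 degrees, and
# randomized relative to the reference. Ground truth is known by
# construction, so every downstream analysis can be checked against what
# was planted. Files go to scratch/demo (regenerable at any time).

library(motioncons)

seed <- 20260923L
demo_dir <- "scratch/demo"
cfg <- make_demo_dataset(demo_dir, seed = seed, n_frames = 400L)

files <- list.files(demo_dir)
cat(sprintf("wrote %d files to %s (seed %d)\n", length(files), demo_dir, seed))
cat(sprintf("trajectories: %d x 400-frame multi-model PDB, 135 atoms each\n",
            sum(grepl("_traj", files))))
cat("config:", cfg, "\n")
cat("systems: wt (reference) + {mod-ident, mod-swap, mod-rot45, mod-rand} x {S, R}\n")
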