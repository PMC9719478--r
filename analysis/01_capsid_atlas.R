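#!/usr/bin/env Rscript
# Which icosahedral capsid architectures are available to a pseudo-hexameric
# trimeric major capsid protein?
#
# Enumerates every Caspar-Klug design up to T = 28, runs the geometric
# two-/three-fold occupancy tests and the hexamer-complexity classification,
# and writes the atlas. Findings printed at the end: the trimer constraint
# blocks T = 4, 12, 16, 28; complexity > 2 removes T = 12, 19, 27; the six
# smallest surviving designs are T = 3, 7, 9, 13, 21, 25, with T = 21 the
# smallest observed for lipid-containing double jelly-roll phages.

suppressPackageStartupMessages(library(capsidlattice))
dir.create("results", showWarnings = FALSE)

group <- build_icosahedral_group()
atlas <- capsid_atlas(28, t_ref = 21, group = group)
write_atlas_tsv(atlas, "results/atlas.tsv")

cat("Capsid architecture atlas (T <= 28), relative to pT = 21:\n\n")
print(atlas, row.names = FALSE, digits = 3)

blocked <- sort(unique(atlas$T[atlas$hex_on_2fold]))
complex <- sort(unique(atlas$T[atlas$Ch > 2]))
allowed <- sort(unique(atlas$T[atlas$allowed]))
cat("\nhexagon on a two-fold axis (trimer placement impossible):",
    paste(blocked, collapse = ", "), "\n")
cat("hexamer complexity > 2 (disfavoured):", paste(complex, collapse = ", "), "\n")
cat("allowed designs:", paste(allowed, collapse = ", "), "\n")
cat(sprintf("relative volume of T = 13 vs T = 21 under the sqrt law: %.1f%%\n",
            100 * atlas$V_rel[atlas$T == 13][1]))

# lattice exports for visualisation
lat41 <- build_capsid_lattice(4, 1, group = group)
model <- build_point_model(lat41, capsid_radius = 300)
write_pdb_points(model, "results/capsid_T21_points.pdb")
cat("\nwrote results/atlas.tsv and results/capsid_T21_points.pdb\n")
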