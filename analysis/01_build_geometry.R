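#!/usr/bin/env Rscript
# Build the characteristic airway geometry: upper airway scaled to the
# 1.56 cm trachea, C-shaped ringed trachea, asymmetric tree to generation 6.
# Writes the morphometry echo and the surface mesh under results/geometry.

suppressPackageStartupMessages(library(airwaydep))

dir.create("results/geometry", recursive = TRUE, showWarnings = FALSE)
cfg <- load_run_config()
obj <- config_objects(cfg)

tree <- characteristic_tree(obj$recipe)
print(tree)
print(summary(tree))

cat("\nupper airway after scaling:\n")
print(tree$upper_airway)
cat(sprintf("C-shape effective tracheal area: %.4f cm^2 (full circle %.4f)\n",
            tree$trachea$csa_effective, pi * (tree$trachea$diameter / 2)^2))
cat(sprintf("rings annotated on trachea: %d, right main bronchus: %d\n",
            ring_count(tree, "T"), ring_count(tree, "RMB")))

write_morphometry(tree$branches[, c("id", "parent_id", "generation",
                                    "length_cm", "diameter_cm", "dx", "dy",
                                    "dz", "lobe", "region")],
                  "results/geometry/characteristic_tree_echo.csv")
export_surface(tree, "results/geometry/airway_surface.stl")
cat("\nwrote results/geometry/{characteristic_tree_echo.csv, airway_surface.stl}\n")
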