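#!/usr/bin/env Rscript
# Build the volume-conductor representations and tabulate their geometry.
#
# Constructs the two tabulated cylinder/slab stacks (subjects 1 and 2) and
# a seeded pseudo-anatomical model, prints the layer radii, and writes the
# projection-averaged fat thickness and bone-to-muscle distance per site —
# the geometric quantities the later comparisons are interpreted against.

suppressPackageStartupMessages({library(stimfield); library(dplyr)})
dir.create("results", showWarnings = FALSE)

models <- list(
  CM1 = build_model("CM", thigh_layers(1)),
  CM2 = build_model("CM", thigh_layers(2)),
  PM1 = build_model("PM", thigh_layers(1)),
  PM2 = build_model("PM", thigh_layers(2)),
  AM_S = generate_pseudo_anatomy(anatomy_params(seed = 7)))

for (nm in names(models)) {
  cat("\n==", nm, "==\n")
  print(models[[nm]])
}

metrics <- bind_rows(lapply(names(models), function(nm) {
  bind_rows(lapply(c("anterior", "posterior", "medial", "lateral"),
                   function(s) tibble::tibble(
    model = nm, site = s,
    fat_thickness_mm = average_fat_thickness(models[[nm]], s),
    bone_to_muscle_mm = average_bone_to_muscle_distance(models[[nm]], s))))
}))
write_table_csv(metrics, "results/geometry_metrics.csv")
cat("\nGeometry metrics (mm):\n")
print(as.data.frame(metrics), digits = 4)

# discrepancy of the simplified stacks against the pseudo-anatomy, per site
disc <- metrics |>
  filter(model != "AM_S") |>
  left_join(filter(metrics, model == "AM_S") |>
              select(site, fat_ref = fat_thickness_mm,
                     bone_ref = bone_to_muscle_mm), by = "site") |>
  mutate(fat_discrepancy_mm = fat_thickness_mm - fat_ref,
         bone_discrepancy_mm = bone_to_muscle_mm - bone_ref)
write_table_csv(disc, "results/geometry_discrepancy.csv")
cat("\nA positive discrepancy means the simplified stack has the larger",
    "average fat thickness / bone distance than the pseudo-anatomy.\n")

# inspection meshes
write_model_obj(models$AM_S, "results/pseudo_anatomy.obj")
cat("wrote results/geometry_metrics.csv, results/geometry_discrepancy.csv,",
    "results/pseudo_anatomy.obj\n")
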