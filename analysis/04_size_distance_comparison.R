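#!/usr/bin/env Rscript
# How well do the simplified stacks track the pseudo-anatomy?
#
# Sweeps electrode size (1-25 cm^2 at 4 cm gap) and interelectrode
# distance (1-56 mm at 25 cm^2) for CM1, PM1 and the seeded
# pseudo-anatomical reference, writes the threshold tables and
# activation-error tables, and cross-correlates the threshold curves —
# the quantitative sense in which a cheap cylinder or slab predicts the
# *tendency* of the anatomical model even when its absolute error is
# large.

suppressPackageStartupMessages({library(stimfield); library(dplyr)})
dir.create("results", showWarnings = FALSE)

models <- list(
  AM_S = generate_pseudo_anatomy(anatomy_params(seed = 7,
                                                axial_length_cm = 24)),
  CM1 = build_model("CM", thigh_layers(1), axial_length_cm = 24),
  PM1 = build_model("PM", thigh_layers(1), axial_length_cm = 24))

areas <- c(1, 2.5, 4, 6.25, 9, 12.25, 16, 20.25, 25)
size_sweep <- run_sweep(sweep_spec(models, reference = "AM_S",
                                   areas_cm2 = areas, gaps_cm = 4,
                                   diameters_um = 12, depths_mm = 5,
                                   base_dof = 5e5))
write_table_csv(size_sweep, "results/threshold_size_curve.csv")
write_table_csv(error_table(size_sweep), "results/error_size_curve.csv")

gaps <- seq(0.1, 5.6, by = 0.5)
dist_sweep <- run_sweep(sweep_spec(models, reference = "AM_S",
                                   areas_cm2 = 25, gaps_cm = gaps,
                                   diameters_um = 12, depths_mm = 5,
                                   base_dof = 3.5e5))
write_table_csv(dist_sweep, "results/threshold_distance_curve.csv")
write_table_csv(error_table(dist_sweep), "results/error_distance_curve.csv")

curve_of <- function(tt, model) tt$threshold_mA[tt$model == model]
xc <- tibble::tibble(
  sweep = rep(c("electrode_size", "interelectrode_distance"), each = 2),
  model = rep(c("CM1", "PM1"), 2),
  pearson_vs_reference = c(
    cross_correlate(curve_of(size_sweep, "CM1"), curve_of(size_sweep, "AM_S")),
    cross_correlate(curve_of(size_sweep, "PM1"), curve_of(size_sweep, "AM_S")),
    cross_correlate(curve_of(dist_sweep, "CM1"), curve_of(dist_sweep, "AM_S")),
    cross_correlate(curve_of(dist_sweep, "PM1"), curve_of(dist_sweep, "AM_S"))))
write_table_csv(xc, "results/cross_correlation.csv")
cat("cross-correlation of threshold curves against the reference:\n")
print(as.data.frame(xc), digits = 4)

err <- error_table(size_sweep)
cat(sprintf("\nmean activation error over the size sweep: CM1 %.1f%%, PM1 %.1f%%\n",
            mean(err$error_pct[err$model == "CM1"]),
            mean(err$error_pct[err$model == "PM1"])))
cat(sprintf("PM threshold exceeds CM at %d of %d size-sweep points\n",
            sum(curve_of(size_sweep, "PM1") > curve_of(size_sweep, "CM1")),
            length(areas)))
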