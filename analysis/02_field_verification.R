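#!/usr/bin/env Rscript
# Verify the field solver against analytic and conservation oracles.
#
# (1) An interior source/sink pair in a homogeneous block must reproduce
#     the closed-form potential I/(4 pi sigma r) (coordinate-scaled for
#     anisotropic muscle) a few millimetres to centimetres from the poles.
# (2) On the layered cylinder, the full injected current must cross any
#     transverse plane between the electrodes, and swapping the electrode
#     roles must negate the field.

suppressPackageStartupMessages(library(stimfield))
dir.create("results", showWarnings = FALSE)

oracle <- function(st, sl, box, poles, offs_mm) {
  dom <- discretize_box(box[1], box[2], box[3], h_cm = 0.2,
                        sigma_t_mSm = st, sigma_l_mSm = sl)
  sol <- solve_point_sources(dom, poles, c(1, -1), source_radius_cm = 0.45)
  pos <- sol$source_points_cm
  cf <- function(p) {
    s_t <- st / 1000; s_l <- sl / 1000; v <- 0
    for (k in 1:2) {
      d <- (p - pos[k, ]) / 100
      v <- v + c(1, -1)[k] /
        (4 * pi * sqrt(s_t) * sqrt(s_l * (d[1]^2 + d[2]^2) + s_t * d[3]^2))
    }
    v
  }
  pts <- sweep(offs_mm / 10, 2, pos[1, ], "+")
  v_num <- sample_along(sol, pts)
  v_cf <- apply(pts, 1, cf)
  r_mm <- sqrt(rowSums(offs_mm^2))
  gauge <- mean((v_num - v_cf)[r_mm >= 10])
  data.frame(r_mm = r_mm, v_num_V = v_num - gauge, v_closed_form_V = v_cf,
             rel_err_pct = 100 * (v_num - gauge - v_cf) / abs(v_cf))
}

offs <- rbind(c(5, 0, 0), c(0, 5, 0), c(8, 0, 0), c(6, 6, 0), c(12, 0, 0),
              c(0, 12, 0), c(16, 0, 0), c(20, 0, 0), c(0, 20, 0))
iso <- oracle(100, 100, c(19, 19, 26),
              rbind(c(0, 0, -2.8), c(0, 0, 2.8)), offs)
iso$medium <- "isotropic"
ani <- oracle(82.38, 329.53, c(26, 19, 38),
              rbind(c(-2.8, 0, 0), c(2.8, 0, 0)), -offs)
ani$medium <- "anisotropic_muscle"
both <- rbind(iso, ani)
write_table_csv(both, "results/field_oracle.csv")
cat(sprintf("point-source oracle: max |rel err| %.2f%% (isotropic), %.2f%% (anisotropic)\n",
            max(abs(iso$rel_err_pct)), max(abs(ani$rel_err_pct))))

cm1 <- build_model("CM", thigh_layers(1), axial_length_cm = 24)
el <- place_electrodes(cm1, "anterior", 9, 4)
dom <- discretize(cm1, el, base_dof = 5e4)
sol <- solve_unit_field(dom)
cat(sprintf("flux through the mid-plane: %.6f A (target 1)\n",
            abs(flux_through_plane(sol, 0))))
cat(sprintf("cathode / anode currents: %.6f / %.6f A\n",
            electrode_current(sol, "proximal"),
            electrode_current(sol, "distal")))
sw <- solve_unit_field(discretize(cm1, swap_electrode_roles(el),
                                  base_dof = 5e4))
cat(sprintf("reciprocity |V + V_swapped| / |V|: %.2e\n",
            max(abs(sw$potential_V + sol$potential_V)) /
              max(abs(sol$potential_V))))
dir.create("scratch", showWarnings = FALSE)
write_field_vtk(sol, "scratch/cm1_lead_field.vtk")  # large; scratch only
cat("wrote results/field_oracle.csv, scratch/cm1_lead_field.vtk\n")
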