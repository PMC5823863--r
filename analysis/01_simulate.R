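#!/usr/bin/env Rscript
# Step 1 — generate the synthetic inputs for the whole workflow:
# a calibration-style solution trace, a ligand solution trace, a
# membrane-positioned trace, the distance/time gradient table and the
# TR-FRET binding plates. Everything downstream reads these files.

suppressPackageStartupMessages(library(micropk))
dir.create("results", showWarnings = FALSE)

seed <- 20260930L

# ligand in solution at the added concentration (1.8 nM, ~1x Kd)
sol <- simulate_solution_trace(
  solution_sim_config(1.8, duration = 20, seed = seed))
write_trace(sol, "results/trace_solution_1.8nM.csv")
cat(sprintf("solution trace: %d bins, mean rate %.1f kHz, %d particles in box\n",
            length(sol), mean_rate(sol) / 1e3, sol$metadata$n_particles_3d))

# membrane-positioned read: free ligand plus a slow, bright 2D component
w0 <- 0.2e-6
mem <- simulate_membrane_trace(membrane_sim_config(
  1.8, surface_density = 0.36 / (pi * w0^2), diffusion_coeff_2d = 5e-13,
  brightness_ratio = 9.1, duration = 20, seed = seed + 1L, box_scale = 8))
write_trace(mem, "results/trace_membrane.csv")
cat(sprintf("membrane trace: mean rate %.1f kHz, %d free + %d bound particles\n",
            mean_rate(mem) / 1e3, mem$metadata$n_particles_3d,
            mem$metadata$n_particles_2d))

# distance/time concentration gradient table (four conditions)
grad <- generate_gradient_dataset(gradient_config(seed = seed))
write_measurements(grad, "results/gradient_measurements.csv")
cat(sprintf("gradient table: %d rows, %d cells\n",
            nrow(grad), length(unique(grad$cell_id))))

# TR-FRET plates: saturation + four association time courses
bind_cfg <- binding_config(seed = seed)
sat <- generate_saturation_dataset(bind_cfg)
write.csv(data.frame(ligand_nM = sat$ligand_concs_nM, total = sat$totals,
                     nsb = sat$nsbs),
          "results/binding_saturation.csv", row.names = FALSE)
tcs <- generate_association_timecourses(bind_cfg)
assoc <- do.call(rbind, lapply(tcs, function(tc)
  data.frame(ligand_nM = tc$ligand_conc_nM, time_min = tc$times_min,
             total = tc$ratio_total, nsb = tc$ratio_nsb)))
write.csv(assoc, "results/binding_association.csv", row.names = FALSE)
cat("binding plates written (saturation + association)\n")
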