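#!/usr/bin/env Rscript
# Step 3 — distance and time profiles of the local ligand concentration, and
# the statistical comparisons: t-tests against the added concentration,
# two-way ANOVA over condition x distance, and Tukey/Dunnett post-hoc tests.

suppressPackageStartupMessages(library(micropk))

grad <- read_measurements("results/gradient_measurements.csv")

# distance profiles at the 2-h time point
profiles <- do.call(rbind, lapply(unique(grad$condition), function(cond)
  build_profile(grad, cond, axis = "distance", at = 120)))
write.csv(profiles, "results/gradient_profiles_distance.csv", row.names = FALSE)

near <- profiles[profiles$position == 2 & profiles$condition == "receptor_high", ]
cat(sprintf("receptor-high 2 um: %.1f +/- %.1f nM (n = %d); bulk 200 um: %.2f nM\n",
            near$mean_conc, near$sem_conc, near$n,
            profiles$mean_conc[profiles$position == 200 &
                               profiles$condition == "receptor_high"]))

# t-tests of each near position vs the added 1.8 nM, per condition
tt <- do.call(rbind, lapply(unique(grad$condition), function(cond) {
  sub <- grad[grad$condition == cond & grad$time_min == 120 &
                grad$distance_um <= 5, ]
  do.call(rbind, lapply(split(sub, sub$distance_um), function(g) {
    r <- one_sample_ttest(g$conc_nM, mu0 = 1.8)
    cbind(condition = cond, distance_um = g$distance_um[1], r)
  }))
}))
write.csv(tt, "results/ttests_vs_added.csv", row.names = FALSE)
cat(sprintf("%d of %d near-membrane t-tests reject 1.8 nM at alpha 0.05\n",
            sum(tt$p_value < 0.05), nrow(tt)))

# condition x distance ANOVA at 2 h, with both post-hoc families
at2h <- grad[grad$time_min == 120, ]
aov2 <- two_way_anova(at2h, factor_a = "condition", factor_b = "distance_um")
print(aov2)
tukey <- posthoc(aov2, "tukey")                       # conditions per distance
aovd <- two_way_anova(at2h, factor_a = "distance_um", factor_b = "condition")
dunnett <- posthoc(aovd, "dunnett", reference = "200") # distances vs bulk
write.csv(rbind(aov2$tests, tukey, dunnett),
          "results/gradient_stats.csv", row.names = FALSE)
cat(sprintf("Tukey: %d/%d condition contrasts significant; Dunnett vs 200 um: %d/%d\n",
            sum(tukey$p_value < 0.05), nrow(tukey),
            sum(dunnett$p_value < 0.05), nrow(dunnett)))

# time profiles at 2 um
tprof <- do.call(rbind, lapply(unique(grad$condition), function(cond)
  build_profile(grad, cond, axis = "time", at = 2)))
write.csv(tprof, "results/gradient_profiles_time.csv", row.names = FALSE)
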