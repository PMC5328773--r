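#!/usr/bin/env Rscript
# Stage 5: QMR body composition. Per-category proportion summaries and
# hydration ratios (reference means and simulated records), the component
# linear fits, and the origin-preserving two-angle plane rotation of
# lean-fat-water proportion space.
library(bkcolony)

out <- "results"
means <- read.csv(system.file("extdata/composition_means.csv",
                              package = "bkcolony"))
means$hydration <- hydration_ratio(means$total_water_p, means$free_water_p,
                                   means$lean_p)
cat("hydration ratios from the reference category means:\n")
print(data.frame(category = means$category, hydration = round(means$hydration, 3)),
      row.names = FALSE)

qmr <- read_composition("results/colony/composition.csv")
props <- composition_proportions(qmr)
props$hydration <- hydration_ratio(props$total_water_p, props$free_water_p,
                                   props$lean_p)
summ <- aggregate(cbind(lean_p, fat_p, total_water_p, free_water_p, total_p,
                        hydration) ~ category, props, mean)
write.table(summ, file.path(out, "composition_summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

wt <- props[props$category %in% c("mWT", "fWT"), ]
f_fat <- linear_fit(wt$lean_p, wt$fat_p)
cat(sprintf("\nfat vs lean (mWT+fWT): slope %.3f, x-intercept %.3f, r2 %.3f\n",
            f_fat$slope, f_fat$x_intercept, f_fat$r_squared))
m <- props[props$category %in% c("mWT", "mhet"), ]
f_w <- linear_fit(m$lean_p, m$specific_water_p)
cat(sprintf("specific water vs lean (mWT+mhet): slope %.3f, x-intercept %.3f\n",
            f_w$slope, f_w$x_intercept))

fitset <- props[props$category %in% c("mWT", "fWT", "mhet", "fhet"), ]
plane <- fit_plane_rotation(fitset$lean_p, fitset$fat_p, fitset$specific_water_p)
cat("\nplane rotation fitted to WT and het mice:\n")
print(plane)
jsonlite::write_json(
  list(phi = plane$phi, psi = plane$psi,
       coefficients = as.list(plane$coefficients),
       residual_ss = plane$residual_ss),
  file.path(out, "plane_fit.json"), auto_unbox = TRUE, digits = NA)
cat("plane fit ->", file.path(out, "plane_fit.json"), "\n")
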