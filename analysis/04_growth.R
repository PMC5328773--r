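#!/usr/bin/env Rscript
# Stage 4: post-weaning growth. Weekly fractional gains, the <2% growth-pause
# rule, first-pause distributions per category, littermate KO-WT weight
# deltas, and average-shifted-histogram weight densities at 8 weeks.
library(bkcolony)

out <- "results"
colony <- read_colony("results/colony")
weights <- read_weights("results/colony/weights.csv")

gains <- weekly_gains(weights, threshold = 0.02)
cats <- unique(weights$category)
cat("first growth pause by 9 weeks of age:\n")
for (cc in sort(cats)) {
  ids <- unique(weights$mouse_id[weights$category == cc])
  fp <- first_pause_distribution(gains[gains$mouse_id %in% ids, ], cutoff_week = 9)
  cat(sprintf("  %-5s n = %3d, proportion = %.2f\n", cc, fp$n_mice,
              fp$proportion_by_cutoff))
}

mice <- unique(weights[, c("mouse_id", "category")])
mice$litter_id <- colony$pups$litter_id[match(mice$mouse_id, colony$pups$pup_id)]
for (contrast in list(c("mKO", "mWT"), c("fKO", "fWT"), c("fWT", "mWT"))) {
  d <- littermate_deltas(weights, mice, contrast)
  lbl <- paste(contrast, collapse = "-")
  adult <- d[d$week >= 10 & d$week <= 15, ]
  cat(sprintf("littermate %s delta, weeks 10-15: %+.2f g (mean of weekly means)\n",
              lbl, mean(adult$mean_delta)))
  write.table(d, file.path(out, paste0("deltas_", lbl, ".tsv")), sep = "\t",
              row.names = FALSE, quote = FALSE)
}

# shared-resolution ASH weight densities at 8 weeks (one h per comparison)
wk8 <- weights[weights$age_week == 8, ]
h <- 2 * stats::IQR(wk8$weight_g) / length(unique(wk8$mouse_id))^(1/3)  # FD rule
dens <- do.call(rbind, lapply(sort(cats), function(cc) {
  d <- ash_density(wk8$weight_g[wk8$category == cc], h = h, m = 8)
  data.frame(category = cc, center = d$grid, density = d$density)
}))
write.table(dens, file.path(out, "ash_week8.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("ASH densities at week 8 (h = %.2f g, m = 8) -> %s\n", h,
            file.path(out, "ash_week8.tsv")))
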