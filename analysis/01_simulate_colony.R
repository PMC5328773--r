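#!/usr/bin/env Rscript
# Stage 1: generate the synthetic surveillance colony used by the later
# stages. Defaults emulate the real colony's printed summary structure:
# 110 litters (73 construction / 37 quiescent), litter size 8.5 +/- 2.0,
# two-peak death hazard with a doubled early risk under construction.
library(bkcolony)

seed <- 1
out <- "results/colony"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

colony <- simulate_colony(colony_config(), seed = seed)
write_colony(colony, out)

weights <- simulate_growth(colony$pups, growth_config(), seed = seed)
write.csv(weights, file.path(out, "weights.csv"), row.names = FALSE, quote = FALSE)

adults <- colony$pups[colony$pups$weaned & !is.na(colony$pups$genotype), ]
mice <- data.frame(mouse_id = adults$pup_id,
                   category = pup_category(adults$sex, adults$genotype))
qmr <- simulate_composition(mice, composition_config(), seed = seed)
write.csv(qmr, file.path(out, "composition.csv"), row.names = FALSE, quote = FALSE)

sizes <- table(colony$pups$litter_id)
cat(sprintf("colony: %d litters, %d pups born (litter size %.1f +/- %.1f)\n",
            nrow(colony$litters), nrow(colony$pups), mean(sizes), sd(sizes)))
cat(sprintf("weaned: %d (%.0f%%); weight series: %d mice; QMR records: %d\n",
            sum(colony$pups$weaned), 100 * mean(colony$pups$weaned),
            length(unique(weights$mouse_id)), nrow(qmr)))
cat("records written under", out, "\n")
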