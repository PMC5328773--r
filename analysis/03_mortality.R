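#!/usr/bin/env Rscript
# Stage 3: pup mortality. Daily death timecourse with the P9 early/late
# demarcation, per-period death proportions, litter success by parity, and
# the five-litter running average of early-death proportions over time.
library(bkcolony)

out <- "results"
colony <- read_colony("results/colony")

tc <- death_timecourse(colony$pups)
cat(sprintf("deaths: %d early (incl. %d undated), %d late (boundary P%d)\n",
            tc$early, tc$undated, tc$late, tc$boundary))
write.table(tc$by_day, file.path(out, "mortality_timecourse.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

pp <- period_proportions(colony$pups, colony$litters)
print(pp, row.names = FALSE)
ratio <- pp$early_prop[pp$period == "construction"] /
  pp$early_prop[pp$period == "quiescent"]
cat(sprintf("early-death proportion ratio construction/quiescent: %.2f\n", ratio))
write.table(pp, file.path(out, "mortality_periods.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

ls <- litter_success(colony$litters, colony$pups)
cat(sprintf("total-loss litters: %d of %d; first litters among them: %d\n",
            sum(ls$per_litter$total_loss), nrow(ls$per_litter),
            sum(ls$per_litter$total_loss & ls$per_litter$first_litter)))
write.table(ls$by_parity, file.path(out, "litter_success_by_parity.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

# chronological smoothing of per-litter early-death proportions
ord <- order(colony$litters$birth_date)
lids <- colony$litters$litter_id[ord]
early_prop <- vapply(lids, function(id) {
  lp <- colony$pups[colony$pups$litter_id == id, ]
  ltc <- death_timecourse(lp)
  if (nrow(lp)) ltc$early / nrow(lp) else NA_real_
}, 0)
smooth <- running_average(early_prop, window = 5)
write.table(data.frame(litter_id = lids, early_prop = early_prop,
                       running_avg = smooth),
            file.path(out, "early_death_running_average.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("running-average chronology ->",
    file.path(out, "early_death_running_average.tsv"), "\n")
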