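#!/usr/bin/env Rscript
# Stage 2: Mendelian segregation analysis. First reproduces the published
# count-table statistics from the shipped reference tabulations, then runs
# the same machinery (standard model, Mendelian2, deviation ratios, litter
# sorting) over the simulated colony from stage 1.
library(bkcolony)

out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
extdata <- function(f) system.file("extdata", f, package = "bkcolony")
as_counts <- function(df)
  setNames(as.integer(df$count), df$category)[gender_categories("six")]

## reference tables ----------------------------------------------------------
weaned <- as_counts(read.csv(extdata("weaned_counts.csv")))
cat("== weaned pups: standard Mendelian model ==\n")
print(chi_square_fit(weaned))
cat("\n== weaned pups: Mendelian2 ==\n")
m2 <- mendelian2_estimate(weaned)
print(m2)
cat("\nmale proportion among weaned pups:\n")
sr <- sex_ratio_test(329, 295)
cat(sprintf("  %.1f%% (chi2 = %.2f, P = %.2f)\n",
            100 * sr$male_prop, sr$chi2, sr$p_value))

geno <- read.csv(extdata("genotyped_counts.csv"))
for (set in unique(geno$set)) {
  counts <- as_counts(geno[geno$set == set, ])
  fit <- chi_square_fit(counts)
  m2s <- mendelian2_estimate(counts)
  cat(sprintf("\n== genotyped pups [%s]: chi2 %.2f (P = %.3f), Mendelian2 total %d ==\n",
              set, fit$total_chi2, fit$p_value, m2s$refined_total))
}

early <- read.csv(extdata("early_death_counts.csv"))
efit <- chi_square_fit(setNames(as.integer(early$count), early$genotype))
cat(sprintf("\nearly-death genotypes: chi2 %.2f, P = %.3f (KO flagged: %s)\n",
            efit$total_chi2, efit$p_value, "KO" %in% efit$flagged))

## simulated colony ----------------------------------------------------------
colony <- read_colony("results/colony")
counts <- tally_categories(colony$pups, filter = colony$pups$weaned)
simfit <- chi_square_fit(counts)
simm2 <- mendelian2_estimate(counts)
cat(sprintf("\nsimulated colony weaned tally: chi2 %.2f (P = %.3g), Mendelian2 %d vs observed %d\n",
            simfit$total_chi2, simfit$p_value, simm2$refined_total, sum(counts)))

complete8 <- sort_litters(colony$litters, colony$pups,
                          function(s) s$complete & s$size >= 8)
dr <- litter_deviation_ratios(
  colony$pups[colony$pups$litter_id %in% complete8$litter_id, ], complete8)
write.table(dr$summary, file.path(out, "deviation_ratios.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("deviation ratios over %d complete litters (>=8 pups) -> %s\n",
            nrow(complete8), file.path(out, "deviation_ratios.tsv")))
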