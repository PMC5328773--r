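# Shared fixtures: printed reference tabulations of the BK colony records,
# and small in-code colony builders.

weaned_counts <- c(mWT = 102L, fWT = 88L, mhet = 168L, fhet = 145L,
                   mKO = 59L, fKO = 62L)                      # 624 weaned
early_death_counts <- c(WT = 9L, het = 18L, KO = 19L)         # 46 genotyped
quiescent_early_counts <- c(WT = 4L, het = 14L, KO = 17L)     # 35 genotyped
construction_complete_counts <- c(mWT = 25L, fWT = 15L, mhet = 40L,
                                  fhet = 20L, mKO = 13L, fKO = 24L)  # 137
quiescent_complete_counts <- c(mWT = 23L, fWT = 18L, mhet = 44L,
                               fhet = 39L, mKO = 19L, fKO = 13L)     # 156

# a tiny hand-built colony: two litters, one death each, one unknown genotype
tiny_colony <- function() {
  litters <- data.frame(
    litter_id = c("L1", "L2"),
    dam_id = c("D1", "D2"),
    parity = c(1L, 2L),
    birth_date = as.Date(c("2013-04-02", "2014-11-20")),
    period = c("construction", "quiescent"),
    complete = c(TRUE, FALSE))
  pups <- data.frame(
    pup_id = sprintf("P%02d", 1:13),
    litter_id = c(rep("L1", 6), rep("L2", 7)),
    sex = c("M", "M", "F", "F", "M", "F", "F", "M", "M", "F", "M", "F", "M"),
    genotype = c("WT", "het", "het", "WT", "KO", "KO",
                 "WT", "het", "het", "KO", "WT", NA, "KO"),
    death_day = c(NA, NA, NA, NA, 14L, NA, NA, NA, NA, 13L, NA, 1L, NA),
    weaned = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
               TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  list(litters = litters, pups = pups)
}

# build a perfectly Mendelian litter of size 8: one of each 1/8 category,
# two of each 1/4 category
mendelian_litter_pups <- function(litter_id, counts = c(1, 1, 2, 2, 1, 1)) {
  cats <- gender_categories("six")
  sex <- rep(substr(cats, 1, 1), counts)
  geno <- rep(sub("^[mf]", "", cats), counts)
  n <- sum(counts)
  data.frame(pup_id = paste0(litter_id, "_", seq_len(n)),
             litter_id = litter_id,
             sex = ifelse(sex == "m", "M", "F"),
             genotype = geno,
             death_day = NA_integer_,
             weaned = TRUE)
}
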