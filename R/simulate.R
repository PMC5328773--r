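#' Configuration for the synthetic breeding colony
#'
#' Defaults emulate the surveillance summary statistics of the het-by-het
#' BK-channel colony: 110 litters split 73 construction / 37 quiescent,
#' litter sizes 8.5 +/- 2.0 (rounded truncated normal, minimum 1), 50:50
#' sexes, 1:2:1 genotypes, a two-peak daily death hazard (geometric decay
#' from P1; symmetric bump near P13), construction doubling the early risk,
#' KO-weighted genotype multipliers calibrated to the printed aggregate
#' death proportions, episodic total-litter losses concentrated in the
#' construction period, a first-litter penalty, and the observed
#' early-death bookkeeping (only ~19.6% of early deaths genotyped; ~16% of
#' early deaths undated).
#'
#' `ko_prenatal_deletion` removes that fraction of KO conceptuses before
#' birth — a non-Mendelian loss channel invisible to the standard model and
#' the scenario the Mendelian2 estimator targets.
#'
#' @param n_litters number of litters.
#' @param construction_fraction fraction of litters born during
#'   construction (assigned chronologically first).
#' @param litter_size_mean,litter_size_sd conception litter size (pups).
#' @param p_male probability a conceptus is male.
#' @param genotype_fractions WT/het/KO fractions of the het-by-het cross.
#' @param ko_prenatal_deletion probability a KO conceptus dies prenatally.
#' @param early_risk_quiescent per-pup probability of an early (P0-P8)
#'   death in the quiescent period, before genotype multipliers.
#' @param construction_early_ratio multiplier on early risk during
#'   construction.
#' @param early_genotype_mult,late_genotype_mult named genotype risk
#'   multipliers (population-weighted mean 1 under 1:2:1).
#' @param late_risk per-pup probability of a late (P9-P21) death.
#' @param p_total_loss named per-period probability a litter is lost whole.
#' @param first_litter_mult early-risk multiplier for a dam's first litter.
#' @param p_genotyped_early probability an early death is genotyped.
#' @param p_undated_early probability an early death has no recorded day.
#' @param boundary early/late demarcation day.
#' @param start_date birth date of the first litter; litters arrive every
#'   `days_between_litters` days.
#' @param days_between_litters spacing of litter birth dates.
#' @return a `colony_config` list.
#' @export
colony_config <- function(n_litters = 110,
                          construction_fraction = 73 / 110,
                          litter_size_mean = 8.5,
                          litter_size_sd = 2.0,
                          p_male = 0.5,
                          genotype_fractions = c(WT = 0.25, het = 0.5, KO = 0.25),
                          ko_prenatal_deletion = 0,
                          early_risk_quiescent = 0.125,
                          construction_early_ratio = 2.0,
                          early_genotype_mult = c(WT = 0.5, het = 0.8, KO = 1.9),
                          late_genotype_mult = c(WT = 0.3, het = 0.5, KO = 2.7),
                          late_risk = 0.05,
                          p_total_loss = c(construction = 0.09, quiescent = 0.02),
                          first_litter_mult = 1.3,
                          p_genotyped_early = 0.196,
                          p_undated_early = 37 / 235,
                          boundary = 9,
                          start_date = as.Date("2013-03-01"),
                          days_between_litters = 6) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(genotype_fractions) - 1) < 1e-12,
            all(unlist(cfg[c("p_male", "ko_prenatal_deletion",
                             "early_risk_quiescent", "late_risk",
                             "p_genotyped_early", "p_undated_early")]) >= 0),
            early_risk_quiescent * construction_early_ratio *
              max(early_genotype_mult) * first_litter_mult < 1)
  class(cfg) <- "colony_config"
  cfg
}

# deterministic child seeds so partial regeneration is stable
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + stage * 101L
}

# geometric decay from P1 over days 0..8
early_day_weights <- function(boundary = 9, decay = 0.55) {
  d <- 0:(boundary - 1)
  w <- decay^abs(d - 1)
  w / sum(w)
}

# symmetric bump peaking at P13 over days boundary..21
late_day_weights <- function(boundary = 9, peak = 13, width = 2.5) {
  d <- boundary:21
  w <- exp(-((d - peak)^2) / (2 * width^2))
  w / sum(w)
}

#' Simulate a breeding colony (litters and pups)
#'
#' Draws litters and pups under a [colony_config()]: litter sizes from a
#' rounded truncated normal, independent sex and genotype per conceptus,
#' optional prenatal KO deletion, and death days from the two-peak daily
#' hazard with period/genotype/parity multipliers. Total-loss litters lose
#' every pup in the early window. Surviving pups are weaned (alive at P21;
#' KO pups stay with dams to ~P28 but that is a husbandry flag, not a
#' survival difference). Early deaths are genotyped only with the
#' configured probability (others keep `genotype = NA`) and may be undated.
#' Fully reproducible per seed; the truth needed by recovery studies is
#' attached as attributes.
#'
#' @param config a [colony_config()].
#' @param seed integer seed; child streams per stage are derived from it.
#' @return `list(litters, pups)` in the standard record schemas. The pup
#'   table carries `genotype` (observed; NA when not genotyped) plus a
#'   `genotype_true` column; attribute `conception_total` on the list gives
#'   the true conception-cohort size including prenatally deleted pups.
#' @export
simulate_colony <- function(config = colony_config(), seed = 1) {
  cfg <- config
  n <- cfg$n_litters
  n_con <- round(cfg$construction_fraction * n)

  set.seed(derive_seed(seed, 1L))
  sizes <- pmax(1L, as.integer(round(stats::rnorm(n, cfg$litter_size_mean,
                                                  cfg$litter_size_sd))))
  period <- c(rep("construction", n_con), rep("quiescent", n - n_con))
  dam_pool <- paste0("D", sprintf("%03d", seq_len(max(1, ceiling(n / 4)))))
  dam <- rep(dam_pool, length.out = n)
  parity <- stats::ave(seq_len(n), dam, FUN = seq_along)
  litters <- data.frame(
    litter_id = paste0("L", sprintf("%03d", seq_len(n))),
    dam_id = dam,
    parity = as.integer(parity),
    birth_date = cfg$start_date + (seq_len(n) - 1L) * cfg$days_between_litters,
    period = period,
    complete = NA)

  # conceptions
  set.seed(derive_seed(seed, 2L))
  conception_total <- sum(sizes)
  litter_id <- rep(litters$litter_id, sizes)
  sex <- ifelse(stats::runif(conception_total) < cfg$p_male, "M", "F")
  genotype <- sample(names(cfg$genotype_fractions), conception_total,
                     replace = TRUE, prob = cfg$genotype_fractions)
  deleted <- genotype == "KO" &
    stats::runif(conception_total) < cfg$ko_prenatal_deletion
  litter_id <- litter_id[!deleted]; sex <- sex[!deleted]
  genotype <- genotype[!deleted]
  n_born <- length(litter_id)

  # postnatal deaths
  set.seed(derive_seed(seed, 3L))
  li <- match(litter_id, litters$litter_id)
  early_base <- ifelse(litters$period[li] == "construction",
                       cfg$early_risk_quiescent * cfg$construction_early_ratio,
                       cfg$early_risk_quiescent)
  early_p <- pmin(0.95, early_base * cfg$early_genotype_mult[genotype] *
                    ifelse(litters$parity[li] == 1, cfg$first_litter_mult, 1))
  late_p <- pmin(0.95, cfg$late_risk * cfg$late_genotype_mult[genotype])
  lost_litter <- stats::runif(n) < cfg$p_total_loss[litters$period]
  dies_early <- stats::runif(n_born) < early_p | lost_litter[li]
  dies_late <- !dies_early & stats::runif(n_born) < late_p

  death_day <- rep(NA_integer_, n_born)
  ne <- sum(dies_early)
  if (ne) death_day[dies_early] <- sample(0:(cfg$boundary - 1), ne, TRUE,
                                          early_day_weights(cfg$boundary))
  nl <- sum(dies_late)
  if (nl) death_day[dies_late] <- sample(cfg$boundary:21, nl, TRUE,
                                         late_day_weights(cfg$boundary))

  # observation process: most early deaths go ungenotyped (dams scavenge
  # newborns), but pups dying on or after the genotyping day (~P6) were
  # already tail-clipped and are always categorized
  geno_day <- 6L
  set.seed(derive_seed(seed, 4L))
  genotyped <- rep(TRUE, n_born)
  early_pre <- dies_early & death_day < geno_day
  genotyped[early_pre] <- stats::runif(sum(early_pre)) < cfg$p_genotyped_early
  undated <- early_pre & stats::runif(n_born) < cfg$p_undated_early
  observed_day <- death_day
  observed_day[undated] <- NA_integer_

  pups <- data.frame(
    pup_id = paste0("P", sprintf("%04d", seq_len(n_born))),
    litter_id = litter_id,
    sex = sex,
    genotype = ifelse(genotyped, genotype, NA_character_),
    death_day = observed_day,
    weaned = !(dies_early | dies_late),
    genotype_true = genotype,
    stringsAsFactors = FALSE)

  # completeness: no attrition before the genotyping day
  attr_before <- tapply((dies_early | dies_late) &
                          (undated | (!is.na(death_day) & death_day < geno_day)),
                        litter_id, any)
  litters$complete <- !as.logical(attr_before[litters$litter_id]) &
    tabulate(li, nbins = n) > 0
  litters$complete[is.na(litters$complete)] <- FALSE

  out <- list(litters = litters, pups = pups)
  attr(out, "conception_total") <- conception_total
  attr(out, "seed") <- seed
  out
}

#' Growth-curve configuration and simulator
#'
#' Weekly weights follow a Gompertz curve
#' `W(t) = A * exp(-b * exp(-k * t))` per sex-by-genotype category, with the
#' adult asymptote A offset by category (female -3.5 g; KO -5 g male,
#' -4 g female, matching the maintained littermate deficits), plus weekly
#' Gaussian noise. With probability `p_pause` a week is replaced by a pause:
#' the weight moves by a uniform fraction below the 2% threshold, and growth
#' resumes on the underlying curve the following week.
#'
#' @param asymptote_mWT adult asymptote of male wild-types (g).
#' @param female_offset,ko_offset_m,ko_offset_f asymptote offsets (g).
#' @param b,k Gompertz shape and rate (per week).
#' @param noise_sd weekly measurement/biology noise (g).
#' @param p_pause per-week pause probability from week 4 on.
#' @param pause_gain_range uniform range of the pause-week fractional gain
#'   (must lie below the 2% pause threshold).
#' @param weeks integer vector of age-weeks measured.
#' @return a `growth_config` list.
#' @export
growth_config <- function(asymptote_mWT = 27,
                          female_offset = -3.5,
                          ko_offset_m = -5,
                          ko_offset_f = -4,
                          b = 2.8, k = 0.35,
                          noise_sd = 0.4,
                          p_pause = 0.08,
                          pause_gain_range = c(-0.02, 0.015),
                          weeks = 3:18) {
  cfg <- as.list(environment())
  stopifnot(asymptote_mWT > 0, noise_sd >= 0,
            all(pause_gain_range < 0.02), p_pause >= 0, p_pause <= 1)
  class(cfg) <- "growth_config"
  cfg
}

category_asymptotes <- function(cfg) {
  A <- cfg$asymptote_mWT
  c(mWT = A, mhet = A, mKO = A + cfg$ko_offset_m,
    fWT = A + cfg$female_offset, fhet = A + cfg$female_offset,
    fKO = A + cfg$female_offset + cfg$ko_offset_f)
}

#' @rdname growth_config
#' @param pups pup record data frame (only weaned, genotyped pups are
#'   weighed).
#' @param config a [growth_config()].
#' @param seed integer seed.
#' @return `simulate_growth()` returns a long weight data frame
#'   (`mouse_id`, `category`, `age_week`, `weight_g`).
#' @export
simulate_growth <- function(pups, config = growth_config(), seed = 1) {
  cfg <- config
  set.seed(derive_seed(seed, 5L))
  keep <- pups$weaned & !is.na(pups$genotype)
  ids <- pups$pup_id[keep]
  cat_of <- pup_category(pups$sex[keep], pups$genotype[keep])
  A <- category_asymptotes(cfg)[cat_of]
  weeks <- cfg$weeks
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    curve <- A[i] * exp(-cfg$b * exp(-cfg$k * weeks)) +
      stats::rnorm(length(weeks), 0, cfg$noise_sd)
    w <- curve
    for (j in seq_along(weeks)[-1]) {
      if (weeks[j] >= 4 && stats::runif(1) < cfg$p_pause) {
        g <- stats::runif(1, cfg$pause_gain_range[1], cfg$pause_gain_range[2])
        w[j] <- w[j - 1] * (1 + g)
      } else {
        w[j] <- curve[j]  # growth resumes on the underlying curve
      }
    }
    out[[i]] <- data.frame(mouse_id = ids[i], category = cat_of[i],
                           age_week = weeks, weight_g = w)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Composition-cloud configuration and simulator
#'
#' Generates QMR records scattered about an oblique plane through the origin
#' of lean-fat-water proportion space. Per-category in-plane centroids
#' default to the colony category means; points are drawn as in-plane
#' coordinates (x', z') around the centroid plus an out-of-plane y'
#' deviation, inverted through the two-angle rotation back to (lean, fat,
#' specific water) proportions, and scaled by a drawn body weight. Free
#' water is drawn small (~0.006 of body weight).
#'
#' @param phi_deg,psi_deg plane rotation angles (degrees).
#' @param centroids data frame `category`, `lean_p`, `fat_p`, `water_p`
#'   (specific water); defaults to the colony category means.
#' @param inplane_sd SD of in-plane scatter (proportion units).
#' @param outplane_sd SD of the out-of-plane deviation y'.
#' @param weight_mean,weight_sd named per-category body-weight draws (g).
#' @param free_water_mean,free_water_sd free-water proportion draw.
#' @return a `composition_config` list.
#' @export
composition_config <- function(phi_deg = 39, psi_deg = 21.5,
                               centroids = default_centroids(),
                               inplane_sd = 0.008,
                               outplane_sd = 0.003,
                               weight_mean = c(mWT = 22.0, mhet = 22.9,
                                               mKO = 17.5, fWT = 18.4,
                                               fhet = 18.5, fKO = 15.5),
                               weight_sd = 1.5,
                               free_water_mean = 0.006,
                               free_water_sd = 0.002) {
  cfg <- as.list(environment())
  stopifnot(inplane_sd >= 0, outplane_sd >= 0)
  class(cfg) <- "composition_config"
  cfg
}

# category mean proportions of the colony (lean, fat, specific water)
default_centroids <- function() {
  data.frame(
    category = c("mWT", "mhet", "mKO", "fWT", "fhet", "fKO"),
    lean_p = c(0.859, 0.857, 0.838, 0.821, 0.825, 0.808),
    fat_p = c(0.074, 0.076, 0.095, 0.097, 0.092, 0.121),
    water_p = c(0.732, 0.732, 0.722, 0.716, 0.726, 0.703))
}

#' @rdname composition_config
#' @param mice data frame with `mouse_id` and `category` (e.g. adult weaned
#'   pups), one QMR record is generated per row.
#' @param config a [composition_config()].
#' @param seed integer seed.
#' @return `simulate_composition()` returns a QMR record data frame in the
#'   `composition.csv` schema.
#' @export
simulate_composition <- function(mice, config = composition_config(), seed = 1) {
  cfg <- config
  set.seed(derive_seed(seed, 6L))
  k <- plane_coefficients(cfg$phi_deg, cfg$psi_deg)
  cen <- cfg$centroids
  idx <- match(mice$category, cen$category)
  if (anyNA(idx)) stop("category without a configured centroid", call. = FALSE)
  cp <- plane_transform(cen$lean_p[idx], cen$fat_p[idx], cen$water_p[idx], k)
  n <- nrow(mice)
  xp <- cp$xp + stats::rnorm(n, 0, cfg$inplane_sd)
  zp <- cp$zp + stats::rnorm(n, 0, cfg$inplane_sd)
  yp <- stats::rnorm(n, 0, cfg$outplane_sd)
  p <- plane_invert(xp, zp, k, yp = yp)
  wt <- stats::rnorm(n, cfg$weight_mean[mice$category], cfg$weight_sd)
  wt <- pmax(wt, 8)
  free_p <- pmax(0, stats::rnorm(n, cfg$free_water_mean, cfg$free_water_sd))
  data.frame(mouse_id = mice$mouse_id,
             category = mice$category,
             total_weight_g = wt,
             lean_g = p$lean * wt,
             fat_g = p$fat * wt,
             total_water_g = (p$water + free_p) * wt,
             free_water_g = free_p * wt)
}
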