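#' Pup mortality timecourse with early/late demarcation
#'
#' Builds the per-day death histogram and its cumulative over the nursing
#' period. A postnatal-day boundary (default 9) demarcates early deaths
#' (day < boundary) from late deaths (day >= boundary). Deaths without a
#' recorded day are assigned to the early period — in the colony record all
#' undated deaths occurred early, typically scavenged newborns.
#'
#' @param pups pup record data frame (birth day is P0; `death_day` NA for
#'   survivors, and a row with `weaned = FALSE` and `death_day = NA` is an
#'   undated death only if flagged by `undated`).
#' @param boundary postnatal day starting the late period.
#' @return list with `by_day` (day, deaths, cumulative), `undated`, `early`
#'   (dated early deaths + undated), `late`, and `boundary`.
#' @export
death_timecourse <- function(pups, boundary = 9) {
  dead <- !pups$weaned
  dated <- dead & !is.na(pups$death_day)
  undated <- sum(dead & is.na(pups$death_day))
  days <- pups$death_day[dated]
  stopifnot(all(days >= 0))
  if (length(days)) {
    tab <- table(factor(days, levels = 0:max(days)))
    by_day <- data.frame(day = as.integer(names(tab)),
                         deaths = as.integer(tab))
    by_day$cumulative <- cumsum(by_day$deaths)
  } else {
    by_day <- data.frame(day = integer(), deaths = integer(),
                         cumulative = integer())
  }
  list(by_day = by_day,
       undated = undated,
       early = sum(days < boundary) + undated,
       late = sum(days >= boundary),
       boundary = boundary)
}

#' Early and late death proportions per colony period
#'
#' Proportion of pups born in a period that died in the early (P0 to
#' boundary-1, plus undated) or late (boundary to weaning) window.
#'
#' @param pups,litters colony record data frames.
#' @param boundary early/late demarcation day.
#' @return data frame with one row per period: `born`, `early_deaths`,
#'   `late_deaths`, `early_prop`, `late_prop`.
#' @export
period_proportions <- function(pups, litters, boundary = 9) {
  per <- litters$period[match(pups$litter_id, litters$litter_id)]
  if (anyNA(per)) stop("pup with unresolved litter_id", call. = FALSE)
  out <- lapply(c("construction", "quiescent"), function(p) {
    sub <- pups[per == p, , drop = FALSE]
    tc <- death_timecourse(sub, boundary)
    data.frame(period = p, born = nrow(sub),
               early_deaths = tc$early, late_deaths = tc$late,
               early_prop = if (nrow(sub)) tc$early / nrow(sub) else NA_real_,
               late_prop = if (nrow(sub)) tc$late / nrow(sub) else NA_real_)
  })
  do.call(rbind, out)
}

#' Litter success: survival to day 3 and to weaning
#'
#' Per-litter born counts, survivors at the end of P3 (deaths on P0 through
#' P3 count against it; undated deaths are treated as early losses before
#' day 3), survivors at weaning, the weaned proportion, a total-loss flag,
#' and a first-litter flag. Parity groups (first through fifth and beyond)
#' are summarized as mean proportion weaned with SEM, split by period.
#'
#' @param litters,pups colony record data frames.
#' @param wean_day nominal weaning age (used only for bookkeeping; weaning is
#'   the recorded `weaned` flag).
#' @return list with `per_litter` (one row per litter) and `by_parity`
#'   (period x parity mean +/- SEM of the weaned proportion).
#' @export
litter_success <- function(litters, pups, wean_day = 21) {
  rows <- lapply(seq_len(nrow(litters)), function(i) {
    lp <- pups[pups$litter_id == litters$litter_id[i], , drop = FALSE]
    born <- nrow(lp)
    died <- !lp$weaned
    early_undated <- died & is.na(lp$death_day)
    dead_by3 <- sum((died & !is.na(lp$death_day) & lp$death_day <= 3) |
                      early_undated)
    weaned <- sum(lp$weaned)
    data.frame(litter_id = litters$litter_id[i],
               period = litters$period[i],
               parity = litters$parity[i],
               born = born,
               surv_day3 = born - dead_by3,
               surv_wean = weaned,
               prop_weaned = if (born) weaned / born else NA_real_,
               total_loss = born > 0 && weaned == 0,
               first_litter = litters$parity[i] == 1)
  })
  per_litter <- do.call(rbind, rows)
  stopifnot(all(per_litter$surv_wean <= per_litter$surv_day3),
            all(per_litter$surv_day3 <= per_litter$born))
  grp <- interaction(per_litter$period, pmin(per_litter$parity, 5), drop = TRUE)
  by_parity <- do.call(rbind, lapply(split(per_litter, grp), function(g) {
    data.frame(period = g$period[1], parity = pmin(g$parity[1], 5),
               n_litters = nrow(g),
               mean_prop_weaned = mean(g$prop_weaned),
               sem = stats::sd(g$prop_weaned) / sqrt(nrow(g)))
  }))
  rownames(by_parity) <- NULL
  list(per_litter = per_litter, by_parity = by_parity)
}

#' Centered running average over a chronological series
#'
#' Five-litter running averages smooth the chronology of per-litter death
#' proportions. The window is centered; at the edges the available neighbors
#' are used (shrunken window), so a constant series is returned unchanged.
#'
#' @param values numeric vector ordered chronologically (by litter birth
#'   date).
#' @param window window size in litters (default 5).
#' @return smoothed numeric vector of the same length.
#' @export
running_average <- function(values, window = 5) {
  stopifnot(window >= 1)
  n <- length(values)
  half <- (window - 1) %/% 2
  upper <- window - 1 - half  # asymmetric halves for even windows
  vapply(seq_len(n), function(i) {
    mean(values[max(1, i - half):min(n, i + upper)])
  }, numeric(1))
}
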