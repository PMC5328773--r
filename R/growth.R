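#' Weekly fractional weight gains and growth pauses
#'
#' The gain over a consecutive week pair is `(w[t+1] - w[t]) / w[t]`,
#' dimensionless with respect to the beginning weight. A week is a growth
#' pause when the gain is strictly below the threshold (default 2%); weight
#' losses are pauses. Gains are defined only for consecutive observed weeks —
#' missing weeks break the computation, no interpolation. The pause is
#' reported at the week of the *ending* weight.
#'
#' @param weights long weight data frame (`mouse_id`, `age_week`,
#'   `weight_g`, optionally `category`).
#' @param threshold pause threshold as a fraction of beginning weight.
#' @return data frame with one row per consecutive week pair: `mouse_id`,
#'   `week` (ending week), `gain`, `pause`.
#' @examples
#' w <- data.frame(mouse_id = "a", age_week = 4:6,
#'                 weight_g = c(15.0, 14.5, 15.2))
#' weekly_gains(w)
#' @export
weekly_gains <- function(weights, threshold = 0.02) {
  weights <- weights[order(weights$mouse_id, weights$age_week), ]
  out <- lapply(split(weights, weights$mouse_id), function(s) {
    if (nrow(s) < 2) return(NULL)
    consec <- diff(s$age_week) == 1
    gain <- diff(s$weight_g) / utils::head(s$weight_g, -1)
    data.frame(mouse_id = s$mouse_id[1],
               week = s$age_week[-1][consec],
               gain = gain[consec])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$pause <- out$gain < threshold
  out
}

#' First-pause week per mouse and its population distribution
#'
#' `first_pause_week()` reduces a gain table to the earliest pause week of
#' each mouse (NA when a mouse never paused). `first_pause_distribution()`
#' histograms those weeks and reports the cumulative proportion of mice whose
#' first pause occurred by a cutoff week (each mouse contributes at most one
#' first pause; mice that never paused stay in the denominator).
#'
#' @param gains output of [weekly_gains()].
#' @param cutoff_week cutoff for the cumulative proportion (default 9).
#' @return `first_pause_week()`: data frame `mouse_id`, `first_pause_week`.
#'   `first_pause_distribution()`: list with `histogram` (week, n),
#'   `n_mice`, and `proportion_by_cutoff`.
#' @export
first_pause_week <- function(gains) {
  out <- do.call(rbind, lapply(split(gains, gains$mouse_id), function(s) {
    wk <- s$week[s$pause]
    data.frame(mouse_id = s$mouse_id[1],
               first_pause_week = if (length(wk)) min(wk) else NA_integer_)
  }))
  rownames(out) <- NULL
  out
}

#' @rdname first_pause_week
#' @export
first_pause_distribution <- function(gains, cutoff_week = 9) {
  fp <- first_pause_week(gains)
  wk <- fp$first_pause_week[!is.na(fp$first_pause_week)]
  hist <- if (length(wk)) {
    tab <- table(wk)
    data.frame(week = as.integer(names(tab)), n = as.integer(tab))
  } else data.frame(week = integer(), n = integer())
  list(histogram = hist,
       n_mice = nrow(fp),
       proportion_by_cutoff = sum(wk <= cutoff_week) / nrow(fp))
}

#' Littermate weight deltas by category contrast
#'
#' Pairs mice of two categories within each litter (all cross pairs when a
#' litter holds several of either category) and summarizes the weekly weight
#' difference `contrast[1] - contrast[2]` as mean +/- SEM across pairs. This
#' paired design controls litter effects; the SEM uses the pair count. A
#' litter-level option averages each litter's pair deltas first, so every
#' litter contributes one observation.
#'
#' @param weights long weight data frame with `mouse_id`, `age_week`,
#'   `weight_g`.
#' @param mice data frame mapping `mouse_id` to `litter_id` and `category`.
#' @param contrast length-2 character vector of categories, e.g.
#'   `c("mKO", "mWT")`.
#' @param level `"pairs"` (default) or `"litter"`.
#' @return data frame per week: `week`, `mean_delta`, `sem`, `n`.
#' @export
littermate_deltas <- function(weights, mice, contrast, level = c("pairs", "litter")) {
  level <- match.arg(level)
  stopifnot(length(contrast) == 2)
  # the mice mapping is authoritative for litter and category; drop any
  # category column the weight table itself carries before joining
  weights <- weights[, c("mouse_id", "age_week", "weight_g")]
  wk <- merge(weights, mice[, c("mouse_id", "litter_id", "category")],
              by = "mouse_id")
  deltas <- NULL
  for (lid in unique(wk$litter_id)) {
    a_ids <- unique(wk$mouse_id[wk$litter_id == lid & wk$category == contrast[1]])
    b_ids <- unique(wk$mouse_id[wk$litter_id == lid & wk$category == contrast[2]])
    if (!length(a_ids) || !length(b_ids)) next
    for (a in a_ids) for (b in b_ids) {
      wa <- wk[wk$mouse_id == a, c("age_week", "weight_g")]
      wb <- wk[wk$mouse_id == b, c("age_week", "weight_g")]
      m <- merge(wa, wb, by = "age_week", suffixes = c("_a", "_b"))
      if (!nrow(m)) next
      deltas <- rbind(deltas, data.frame(
        litter_id = lid, week = m$age_week,
        delta = m$weight_g_a - m$weight_g_b))
    }
  }
  if (is.null(deltas)) return(data.frame(week = integer(), mean_delta = numeric(),
                                         sem = numeric(), n = integer()))
  if (level == "litter") {
    deltas <- stats::aggregate(delta ~ litter_id + week, deltas, mean)
  }
  out <- do.call(rbind, lapply(split(deltas, deltas$week), function(g) {
    data.frame(week = g$week[1], mean_delta = mean(g$delta),
               sem = if (nrow(g) > 1) stats::sd(g$delta) / sqrt(nrow(g)) else NA_real_,
               n = nrow(g))
  }))
  rownames(out) <- NULL
  out[order(out$week), ]
}

#' Average shifted histogram density estimate
#'
#' The ASH estimator averages m ordinary histograms of bin width h whose
#' origins are shifted by h/m. On the fine grid of width h/m this average
#' collapses to a triangular-weighted count smooth: density at fine bin k is
#' `(1/(n h)) * sum_{|i| < m} (1 - |i|/m) * c[k + i]`, where `c` are fine-bin
#' counts. The result is a nonnegative step density on the fine-bin centers
#' integrating to 1. Used for category weight distributions, where one h is
#' shared by all categories in a comparison so their resolutions match.
#'
#' @param values numeric sample (grams, for weight distributions).
#' @param h histogram bin width (same units as `values`).
#' @param m number of shifts (fine bins per bin; default 8).
#' @param origin optional left edge of the fine grid; defaults to
#'   `min(values) - h`, and the grid extends to `max(values) + h` so the
#'   density decays to zero inside the grid.
#' @return object of class `ash_density`: `grid` (fine-bin centers),
#'   `density`, `h`, `m`, `n`.
#' @examples
#' d <- ash_density(c(20.1, 21.3, 22.0), h = 1, m = 8)
#' sum(d$density) * d$h / d$m # ~1
#' @export
ash_density <- function(values, h, m = 8, origin = NULL) {
  stopifnot(length(values) >= 1, h > 0, m >= 1, m == round(m))
  n <- length(values)
  delta <- h / m
  if (is.null(origin)) origin <- min(values) - h
  nbin <- ceiling((max(values) + h - origin) / delta) + 1
  idx <- floor((values - origin) / delta) + 1
  counts <- tabulate(idx, nbins = nbin)
  w <- 1 - abs(seq.int(-(m - 1), m - 1)) / m
  padded <- c(numeric(m - 1), counts, numeric(m - 1))
  smooth <- vapply(seq_len(nbin), function(k) sum(w * padded[k:(k + 2 * m - 2)]),
                   numeric(1))
  out <- list(grid = origin + (seq_len(nbin) - 0.5) * delta,
              density = smooth / (n * h), h = h, m = m, n = n)
  class(out) <- "ash_density"
  out
}

#' Combine independent standard errors in quadrature
#'
#' SEM of a difference of two independent group means: `sqrt(a^2 + b^2)`,
#' as used for construction-minus-quiescent weight deltas.
#'
#' @param sem_a,sem_b standard errors (>= 0).
#' @return combined SEM.
#' @examples
#' sem_combine(3, 4) # 5
#' @export
sem_combine <- function(sem_a, sem_b) {
  stopifnot(all(sem_a >= 0), all(sem_b >= 0))
  sqrt(sem_a^2 + sem_b^2)
}
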