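#' Expected Mendelian category counts
#'
#' For a het-by-het cross the expected count in category *c* is
#' `total * fraction_c`, with fractions 1/8 (sex-specific WT and KO), 1/4
#' (sex-specific het), or 1/4 : 1/2 : 1/4 for collapsed genotypes. Expected
#' counts are never rounded in computation; rounding is display-only.
#'
#' @param total number of categorized pups (or an alternative cohort size).
#' @param scheme `"six"` or `"three"`.
#' @return named numeric vector of expected counts summing to `total`.
#' @examples
#' mendelian_expected(624, "six")
#' mendelian_expected(46, "three")
#' @export
mendelian_expected <- function(total, scheme = c("six", "three")) {
  stopifnot(total >= 0)
  total * category_fractions(match.arg(scheme))
}

#' Chi-square goodness of fit to a Mendelian expectation
#'
#' Decomposes the chi-square statistic into per-category components
#' `(obs - exp)^2 / exp`, computes the upper-tail p-value at
#' `df = categories - 1`, and flags categories whose individual component
#' exceeds 3.84 (the P = 0.05 value at one degree of freedom), the rule used
#' to mark major contributors to a falsified null.
#'
#' @param observed named integer vector of category counts.
#' @param expected expected real counts; defaults to the Mendelian expectation
#'   at `sum(observed)`.
#' @param component_threshold flagging threshold for single components.
#' @return an object of class `mendelian_fit`: observed, expected (unrounded),
#'   per-category `components`, `total_chi2`, `df`, `p_value`, and the
#'   `flagged` category names.
#' @examples
#' obs <- c(mWT = 102, fWT = 88, mhet = 168, fhet = 145, mKO = 59, fKO = 62)
#' chi_square_fit(obs)
#' @export
chi_square_fit <- function(observed, expected = NULL,
                           component_threshold = 3.84) {
  k <- length(observed)
  if (is.null(expected)) {
    scheme <- if (k == 6) "six" else if (k == 3) "three" else
      stop("cannot infer scheme; supply expected counts", call. = FALSE)
    expected <- mendelian_expected(sum(observed), scheme)
  }
  stopifnot(length(expected) == k)
  if (any(expected == 0 & observed > 0))
    stop("expected count of zero where observations are present", call. = FALSE)
  components <- ifelse(expected == 0, 0, (observed - expected)^2 / expected)
  names(components) <- names(observed)
  total <- sum(components)
  df <- k - 1
  out <- list(observed = observed, expected = expected,
              components = components, total_chi2 = total, df = df,
              p_value = chi2_sf(total, df),
              flagged = names(components)[components > component_threshold])
  class(out) <- "mendelian_fit"
  out
}

#' @export
print.mendelian_fit <- function(x, ...) {
  tab <- rbind(Observed = x$observed,
               Expected = round(x$expected, 2),
               Delta = round(x$observed - x$expected, 2),
               `Chi-sq` = round(x$components, 2))
  print(tab)
  cat(sprintf("total chi-square = %.2f, df = %d, P = %.3g\n",
              x$total_chi2, x$df, x$p_value))
  if (length(x$flagged))
    cat("components > 3.84:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Mendelian2: cohort-size estimation from presumed-unbiased categories
#'
#' The standard Mendelian model takes the categorized pups as the whole
#' cohort, so pups lost before categorization bias the test. If some
#' categories (by default mWT and mhet) are presumed neither advantaged nor
#' disadvantaged, an alternative total can be obtained from them alone: the
#' seed is `n_ref / sum(reference fractions)` (8/3 of the mWT + mhet count
#' under defaults), then refined by minimizing the sum of the reference
#' categories' chi-square components over integer totals. The refined total
#' estimates the conception cohort whenever losses in the reference
#' categories occurred only by Mendelian (proportion-preserving) mechanisms.
#'
#' @param observed named six-category counts.
#' @param reference character vector of presumed-unbiased categories.
#' @param window optional integer search bounds `c(lo, hi)`; defaults to
#'   `[max(1, ceil(seed/2)), ceil(2*seed)]`.
#' @return an object of class `mendelian2_estimate` with `reference`,
#'   `seed_total`, `refined_total` (smallest minimizer on ties), `objective`
#'   (reference-component sum at the refined total), and `fit` — the full
#'   six-category `mendelian_fit` evaluated at the refined total.
#' @examples
#' obs <- c(mWT = 102, fWT = 88, mhet = 168, fhet = 145, mKO = 59, fKO = 62)
#' mendelian2_estimate(obs)$refined_total # 723
#' @export
mendelian2_estimate <- function(observed, reference = c("mWT", "mhet"),
                                window = NULL) {
  fr <- category_fractions("six")
  if (!length(reference) || !all(reference %in% names(fr)))
    stop("reference must name sex-by-genotype categories", call. = FALSE)
  obs_ref <- observed[reference]
  fr_ref <- fr[reference]
  if (sum(obs_ref) == 0)
    stop("reference categories have zero total; cannot estimate", call. = FALSE)
  seed <- sum(obs_ref) / sum(fr_ref)
  if (is.null(window)) window <- c(max(1, ceiling(seed / 2)), ceiling(2 * seed))
  ns <- seq.int(window[1], window[2])
  objective <- vapply(ns, function(n) sum((obs_ref - n * fr_ref)^2 / (n * fr_ref)),
                      numeric(1))
  best <- ns[which.min(objective)]  # which.min takes the first: smallest n on ties
  out <- list(reference = reference, seed_total = seed, refined_total = best,
              objective = min(objective), window = window,
              fit = chi_square_fit(observed, best * fr))
  class(out) <- "mendelian2_estimate"
  out
}

#' @export
print.mendelian2_estimate <- function(x, ...) {
  cat(sprintf("Mendelian2 estimate: seed %.1f -> refined total %d (reference: %s)\n",
              x$seed_total, x$refined_total, paste(x$reference, collapse = ", ")))
  print(x$fit)
  invisible(x)
}

#' Sex-ratio chi-square test against 50:50
#'
#' @param males,females counts, or pass a pup data frame as `males` and leave
#'   `females` missing to count its `sex` column.
#' @return list with `male_prop`, `chi2` (df 1), and `p_value`.
#' @examples
#' sex_ratio_test(329, 295) # weaned pups: 52.7%, chi2 1.85
#' @export
sex_ratio_test <- function(males, females) {
  if (is.data.frame(males)) {
    females <- sum(males$sex == "F")
    males <- sum(males$sex == "M")
  }
  n <- males + females
  stopifnot(n > 0)
  chi2 <- (males - n / 2)^2 / (n / 2) + (females - n / 2)^2 / (n / 2)
  list(male_prop = males / n, chi2 = chi2, p_value = chi2_sf(chi2, 1))
}

#' Per-litter deviation ratios from Mendelian proportions
#'
#' For each fully categorized litter of size L, the deviation ratio of
#' category *c* is `obs_c / (L * fraction_c)`; 1.0 indicates the expected
#' Mendelian proportion. Ratios are summarized across litters as mean, SEM,
#' and a two-tailed one-sample t-test against 1.0, treating litters as
#' independent observations. A Bonferroni-corrected criterion across the
#' categories is reported alongside the raw p (the screen style used for
#' litter subgroups), with Holm stepdown available via [holm_adjust()].
#'
#' @param pups,litters colony record data frames; only litters whose
#'   `litter_id` appears in `litters` contribute, and each must be fully
#'   genotyped.
#' @param scheme `"six"` or `"three"`.
#' @return list with `ratios` (litters x categories matrix) and `summary`
#'   (per category: mean_ratio, sem, n_litters, p_value, bonferroni
#'   criterion).
#' @export
litter_deviation_ratios <- function(pups, litters, scheme = c("six", "three")) {
  scheme <- match.arg(scheme)
  fr <- category_fractions(scheme)
  ids <- litters$litter_id
  rows <- lapply(ids, function(id) {
    lp <- pups[pups$litter_id == id, , drop = FALSE]
    if (nrow(lp) == 0 || any(is.na(lp$genotype)))
      stop("litter ", id, " is not fully categorized", call. = FALSE)
    counts <- suppressMessages(tally_categories(lp, scheme))
    counts / (nrow(lp) * fr)
  })
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- ids
  m <- ncol(ratios)
  summ <- data.frame(
    category = colnames(ratios),
    mean_ratio = colMeans(ratios),
    sem = apply(ratios, 2, function(v) stats::sd(v) / sqrt(length(v))),
    n_litters = nrow(ratios),
    row.names = NULL)
  summ$p_value <- vapply(seq_len(m), function(j) {
    v <- ratios[, j]
    if (nrow(ratios) < 2 || stats::sd(v) == 0)
      return(if (all(v == 1)) 1 else NA_real_)
    t_test_one(v, mu = 1)$p_value
  }, numeric(1))
  summ$bonferroni_criterion <- 0.05 / m
  list(ratios = ratios, summary = summ)
}

#' Per-litter composition summary and litter sorting
#'
#' `litter_composition()` tabulates, per litter, its size, male count, and
#' six-category counts (joined with the litter's period/completeness flags).
#' `sort_litters()` selects the litters whose summary row satisfies a
#' predicate, preserving input order — the mechanism behind subgroup screens
#' such as "complete litters of at least 8 pups with more than four males".
#'
#' @param litters,pups colony record data frames.
#' @param predicate function taking the per-litter summary data frame and
#'   returning a logical vector over its rows.
#' @return `litter_composition()`: one row per litter. `sort_litters()`: the
#'   subset of `litters` passing the predicate.
#' @examples
#' \dontrun{
#' big <- sort_litters(litters, pups,
#'                     function(s) s$complete & s$size >= 8 & s$males > 4)
#' }
#' @export
litter_composition <- function(litters, pups) {
  cats <- gender_categories("six")
  rows <- lapply(litters$litter_id, function(id) {
    lp <- pups[pups$litter_id == id, , drop = FALSE]
    counts <- if (nrow(lp))
      suppressMessages(suppressWarnings(tally_categories(lp, "six")))
    else stats::setNames(integer(6), cats)
    c(size = nrow(lp), males = sum(lp$sex == "M"), counts)
  })
  comp <- as.data.frame(do.call(rbind, rows))
  cbind(litters[, c("litter_id", "period", "complete", "parity")], comp)
}

#' @rdname litter_composition
#' @export
sort_litters <- function(litters, pups, predicate) {
  comp <- litter_composition(litters, pups)
  keep <- predicate(comp)
  keep[is.na(keep)] <- FALSE
  litters[keep, , drop = FALSE]
}
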