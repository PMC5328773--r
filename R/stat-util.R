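#' Chi-square upper-tail probability
#'
#' Thin wrapper over the chi-square survival function used by every
#' segregation test in the package. At df 1 the flagging threshold 3.84 gives
#' p ~ 0.05, the self-consistency behind the per-category flagging rule.
#'
#' @param statistic chi-square statistic (>= 0).
#' @param df degrees of freedom.
#' @return upper-tail probability.
#' @export
chi2_sf <- function(statistic, df) {
  stopifnot(all(statistic >= 0), all(df >= 1))
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' Student t-tests (one-sample, two-sample, paired)
#'
#' Two-tailed wrappers returning a uniform `(statistic, df, p_value)` list,
#' used by the deviation-ratio and littermate-delta summaries.
#'
#' @param x,y numeric samples.
#' @param mu null mean for the one-sample test.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
t_test_one <- function(x, mu = 0) {
  tt <- stats::t.test(x, mu = mu)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' @rdname t_test_one
#' @export
t_test_two <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' @rdname t_test_one
#' @export
t_test_paired <- function(x, y) {
  if (all(x == y)) return(list(statistic = 0, df = length(x) - 1, p_value = 1))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Trapezoid area under a glucose timecourse
#'
#' Computes the trapezoid-rule area without baseline subtraction. Input
#' concentrations are mmol/L over minutes; output is reported in mole.min/L
#' (the mmol.min/L sum divided by 1000) by default, with `"mmol"` available.
#'
#' @param minutes strictly increasing sample times (min).
#' @param mmol_l glucose concentrations (mmol/L).
#' @param units `"mole"` (default) or `"mmol"`.
#' @return area under the curve in `units`.min/L.
#' @examples
#' auc_trapezoid(c(0, 120), c(5, 5)) # 0.6 mole.min/L
#' @export
auc_trapezoid <- function(minutes, mmol_l, units = c("mole", "mmol")) {
  units <- match.arg(units)
  stopifnot(length(minutes) >= 2, length(minutes) == length(mmol_l),
            all(diff(minutes) > 0), all(minutes >= 0), all(mmol_l >= 0))
  a <- sum(diff(minutes) * (utils::head(mmol_l, -1) + utils::tail(mmol_l, -1)) / 2)
  if (units == "mole") a / 1000 else a
}

#' Holm stepdown (sequentially rejective Bonferroni) adjustment
#'
#' Adjusted p-values for the stepdown Bonferroni multiple-comparison
#' procedure: sort ascending, take the running maximum of
#' `(m - j + 1) * p_(j)`, cap at 1, and map back to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03)) # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "holm")
}
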