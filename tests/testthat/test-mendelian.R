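test_that("Mendelian expected counts are unrounded and sum to the total", {
  expect_equal(as.vector(mendelian_expected(624, "six")),
               c(78, 78, 156, 156, 78, 78), ignore_attr = TRUE)
  expect_equal(as.vector(mendelian_expected(46, "three")),
               c(11.5, 23, 11.5), ignore_attr = TRUE)
  expect_equal(as.vector(mendelian_expected(0, "six")), rep(0, 6),
               ignore_attr = TRUE)
  expect_equal(sum(mendelian_expected(723, "six")), 723)
})

test_that("chi-square decomposition reproduces the weaned-pup table", {
  fit <- chi_square_fit(weaned_counts)
  expect_equal(round(fit$components, 2),
               c(mWT = 7.38, fWT = 1.28, mhet = 0.92, fhet = 0.78,
                 mKO = 4.63, fKO = 3.28))
  # printed total (18.27) is the sum of rounded components; the unrounded
  # total is 18.2756
  expect_equal(sum(round(fit$components, 2)), 18.27)
  expect_equal(fit$total_chi2, 18.2756, tolerance = 1e-4)
  expect_equal(fit$total_chi2, sum(fit$components))
  expect_equal(fit$df, 5)
  expect_setequal(fit$flagged, c("mWT", "mKO"))
})

test_that("three-category fit reproduces the early-death table", {
  fit <- chi_square_fit(early_death_counts)
  expect_equal(round(fit$total_chi2, 2), 6.52)
  expect_equal(fit$df, 2)
  expect_equal(round(fit$p_value, 3), 0.038)
  expect_equal(fit$flagged, "KO")
})

test_that("chi-square fit degenerate and error cases", {
  obs <- c(mWT = 10L, fWT = 10L, mhet = 20L, fhet = 20L, mKO = 10L, fKO = 10L)
  fit <- chi_square_fit(obs)
  expect_equal(unname(fit$components), rep(0, 6))
  expect_equal(fit$p_value, 1)
  expect_error(chi_square_fit(c(a = 1L, b = 0L), expected = c(0, 2)),
               "expected count of zero")
})

test_that("chi-square total is invariant under category permutation", {
  fit <- chi_square_fit(weaned_counts)
  perm <- sample(6)
  fit2 <- chi_square_fit(weaned_counts[perm],
                         expected = mendelian_expected(624, "six")[perm])
  expect_equal(fit2$total_chi2, fit$total_chi2)
})

test_that("Mendelian2 refinement matches brute force over the full window", {
  brute <- function(obs, ref = c("mWT", "mhet"), ns = 1:2000) {
    fr <- category_fractions("six")[ref]
    o <- obs[ref]
    objective <- vapply(ns, function(n) sum((o - n * fr)^2 / (n * fr)), 0)
    ns[which.min(objective)]
  }
  m2 <- mendelian2_estimate(weaned_counts)
  expect_equal(m2$refined_total, 723)
  expect_equal(m2$refined_total, brute(weaned_counts))
  expect_equal(m2$seed_total, (8 / 3) * (102 + 168))
  expect_equal(round(m2$fit$total_chi2, 1), 29.3)
  expect_equal(round(m2$fit$components[["fhet"]], 2), 7.07)

  m2c <- mendelian2_estimate(construction_complete_counts)
  expect_equal(m2c$refined_total, 174)
  expect_equal(m2c$refined_total, brute(construction_complete_counts))

  m2q <- mendelian2_estimate(quiescent_complete_counts)
  expect_equal(m2q$refined_total, 179)
})

test_that("Mendelian2 on perfectly Mendelian counts recovers the exact total", {
  obs <- c(mWT = 10L, fWT = 10L, mhet = 20L, fhet = 20L, mKO = 10L, fKO = 10L)
  m2 <- mendelian2_estimate(obs)
  expect_equal(m2$refined_total, 80)
  expect_equal(m2$objective, 0)
  expect_error(mendelian2_estimate(obs, reference = character()),
               "reference")
  expect_error(mendelian2_estimate(
    c(mWT = 0L, fWT = 5L, mhet = 0L, fhet = 5L, mKO = 1L, fKO = 1L)),
    "zero total")
})

test_that("Mendelian2 objective at the refined total is the window minimum", {
  for (s in 1:3) {
    set.seed(s)
    obs <- stats::setNames(as.integer(rmultinom(1, 120, category_fractions("six"))),
                           gender_categories("six"))
    m2 <- mendelian2_estimate(obs)
    fr <- category_fractions("six")[m2$reference]
    o <- obs[m2$reference]
    allobj <- vapply(seq(m2$window[1], m2$window[2]),
                     function(n) sum((o - n * fr)^2 / (n * fr)), 0)
    expect_equal(m2$objective, min(allobj))
  }
})

test_that("sex-ratio test reproduces the prose statistics", {
  sr <- sex_ratio_test(329, 295)
  expect_equal(round(sr$male_prop, 3), 0.527)
  expect_equal(round(sr$chi2, 2), 1.85)
  expect_equal(round(sr$p_value, 2), 0.17)

  late <- sex_ratio_test(16, 29)  # late-period deaths: 29 female, 16 male
  expect_equal(round(late$chi2, 2), 3.76)
  expect_equal(round(late$p_value, 3), 0.053)

  even <- sex_ratio_test(40, 40)
  expect_equal(even$chi2, 0)
  expect_equal(even$p_value, 1)
})

test_that("per-litter deviation ratios follow obs/(L * fraction)", {
  lit <- data.frame(litter_id = "L1", dam_id = "D", parity = 1L,
                    birth_date = as.Date("2014-01-01"),
                    period = "quiescent", complete = TRUE)
  pups <- mendelian_litter_pups("L1")
  dr <- litter_deviation_ratios(pups, lit)
  expect_equal(unname(dr$ratios[1, ]), rep(1, 6))

  # two complementary litters of 8 average to 1.0 in every category
  lit2 <- rbind(lit, transform(lit, litter_id = "L2"))
  p1 <- mendelian_litter_pups("L1", c(2, 0, 2, 2, 2, 0))
  p2 <- mendelian_litter_pups("L2", c(0, 2, 2, 2, 0, 2))
  dr2 <- litter_deviation_ratios(rbind(p1, p2), lit2)
  expect_equal(unname(dr2$summary$mean_ratio), rep(1, 6))

  # litter of 16: ratios are obs / (16 * fraction)
  p3 <- mendelian_litter_pups("L1", c(4, 0, 4, 4, 2, 2))
  dr3 <- litter_deviation_ratios(p3, lit)
  expect_equal(unname(dr3$ratios[1, ]), c(2, 0, 1, 1, 1, 1))
})

test_that("litter sorting predicates compose as set intersections", {
  sim <- simulate_colony(colony_config(n_litters = 40), seed = 3)
  by_size <- sort_litters(sim$litters, sim$pups, function(s) s$size >= 8)
  by_period <- sort_litters(sim$litters, sim$pups,
                            function(s) s$period == "quiescent")
  by_complete <- sort_litters(sim$litters, sim$pups, function(s) s$complete)
  both <- sort_litters(sim$litters, sim$pups,
                       function(s) s$size >= 8 & s$period == "quiescent" & s$complete)
  expect_setequal(both$litter_id,
                  Reduce(intersect, list(by_size$litter_id, by_period$litter_id,
                                         by_complete$litter_id)))

  # male-count threshold on a hand-built set
  lits <- data.frame(litter_id = c("A", "B", "C"), dam_id = "D", parity = 1L,
                     birth_date = as.Date("2014-01-01"), period = "quiescent",
                     complete = TRUE)
  pups <- rbind(mendelian_litter_pups("A", c(3, 1, 2, 1, 0, 1)),  # 5 males
                mendelian_litter_pups("B", c(1, 2, 2, 2, 0, 1)),  # 3 males
                mendelian_litter_pups("C", c(2, 1, 2, 2, 0, 1)))  # 4 males
  expect_equal(sort_litters(lits, pups, function(s) s$males > 4)$litter_id, "A")
})
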