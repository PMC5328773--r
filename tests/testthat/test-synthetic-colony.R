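test_that("generators are pure functions of (config, seed)", {
  cfg <- colony_config(n_litters = 20)
  a <- simulate_colony(cfg, seed = 123)
  b <- simulate_colony(cfg, seed = 123)
  expect_identical(a$pups, b$pups)
  expect_identical(a$litters, b$litters)
  cdiff <- simulate_colony(cfg, seed = 124)
  expect_false(identical(a$pups, cdiff$pups))

  wa <- simulate_growth(a$pups, seed = 5)
  wb <- simulate_growth(b$pups, seed = 5)
  expect_identical(wa, wb)

  mice <- data.frame(mouse_id = c("x", "y"), category = c("mWT", "fKO"))
  expect_identical(simulate_composition(mice, seed = 2),
                   simulate_composition(mice, seed = 2))
})

test_that("simulated colonies honor the configured structure", {
  cfg <- colony_config(n_litters = 200)
  sim <- simulate_colony(cfg, seed = 31)
  expect_equal(nrow(sim$litters), 200)
  sizes <- table(sim$pups$litter_id)
  expect_equal(mean(sizes), 8.5, tolerance = 0.15)
  expect_equal(sd(sizes), 2.0, tolerance = 0.3)
  expect_true(all(sizes >= 1))
  expect_equal(mean(sim$pups$sex == "M"), 0.5, tolerance = 0.05)
  # every pup resolves; validation passes end to end
  expect_true(validate_colony(sim$pups, sim$litters))
})

test_that("with all hazards zero no pup dies and segregation is Mendelian", {
  cfg <- colony_config(n_litters = 100, early_risk_quiescent = 0,
                       late_risk = 0,
                       p_total_loss = c(construction = 0, quiescent = 0))
  sim <- simulate_colony(cfg, seed = 77)
  expect_true(all(sim$pups$weaned))
  counts <- tally_categories(sim$pups)
  fit <- chi_square_fit(counts)
  expect_gt(fit$p_value, 0.001)  # a fixed healthy colony should not blow up
  expect_equal(sum(counts), nrow(sim$pups))
})

test_that("chi-square rejects at the nominal rate on no-death colonies", {
  cfg <- colony_config(n_litters = 40, early_risk_quiescent = 0,
                       late_risk = 0,
                       p_total_loss = c(construction = 0, quiescent = 0))
  reject <- vapply(1:200, function(s) {
    sim <- simulate_colony(cfg, seed = 1000 + s)
    chi_square_fit(tally_categories(sim$pups))$p_value < 0.05
  }, logical(1))
  rate <- mean(reject)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("Mendelian2 recovers the conception cohort under KO deletion", {
  cfg <- colony_config(n_litters = 300, ko_prenatal_deletion = 0.3,
                       early_risk_quiescent = 0, late_risk = 0,
                       p_total_loss = c(construction = 0, quiescent = 0))
  sim <- simulate_colony(cfg, seed = 55)
  truth <- attr(sim, "conception_total")
  counts <- tally_categories(sim$pups)
  m2 <- mendelian2_estimate(counts)
  expect_lt(abs(m2$refined_total - truth) / truth, 0.04)
  # the standard model's total is the observed count, biased low
  expect_lt(sum(counts), truth * 0.95)
  expect_gt(m2$refined_total, sum(counts))
})

test_that("prenatal deletion leaves male categories at their Mendelian share", {
  cfg <- colony_config(n_litters = 400, ko_prenatal_deletion = 0.5,
                       early_risk_quiescent = 0, late_risk = 0,
                       p_total_loss = c(construction = 0, quiescent = 0))
  sim <- simulate_colony(cfg, seed = 91)
  truth <- attr(sim, "conception_total")
  counts <- tally_categories(sim$pups)
  # mWT + mhet is Binomial(truth, 3/8) regardless of the deletion channel
  expect_equal((counts[["mWT"]] + counts[["mhet"]]) / truth, 3 / 8,
               tolerance = 0.05)
})

test_that("growth generator: smooth curves without noise, pauses when asked", {
  pups <- data.frame(pup_id = c("a", "b"), sex = c("M", "F"),
                     genotype = c("WT", "KO"), weaned = TRUE)
  w <- simulate_growth(pups, growth_config(noise_sd = 0, p_pause = 0), seed = 3)
  g <- weekly_gains(w)
  expect_true(all(g$gain > 0))
  # gains decline toward zero as the curve saturates
  ga <- g$gain[g$mouse_id == "a"]
  expect_true(all(diff(ga) < 0))
  # the saturating curve naturally drops below 2% weekly gain around week 12;
  # earlier weeks must show none without injected pauses
  expect_false(any(g$pause[g$week <= 11]))
})

test_that("composition generator scatters about the configured plane", {
  mice <- data.frame(mouse_id = sprintf("m%03d", 1:120),
                     category = rep(gender_categories("six"), 20))
  cfg <- composition_config(outplane_sd = 0)
  rec <- simulate_composition(mice, cfg, seed = 44)
  expect_true(all(rec$free_water_g <= rec$total_water_g))
  p <- composition_proportions(rec)
  fit <- fit_plane_rotation(p$lean_p, p$fat_p, p$specific_water_p)
  expect_lt(abs(fit$phi - 39), 0.1)
  expect_lt(abs(fit$psi - 21.5), 0.1)

  # out-of-plane noise degrades the fit monotonically
  res <- vapply(c(0.002, 0.01, 0.03), function(sdy) {
    r <- simulate_composition(mice, composition_config(outplane_sd = sdy),
                              seed = 44)
    pp <- composition_proportions(r)
    fit_plane_rotation(pp$lean_p, pp$fat_p, pp$specific_water_p)$residual_ss
  }, 0)
  expect_true(all(diff(res) > 0))

  # zero scatter collapses a category to identical records
  one <- data.frame(mouse_id = c("u", "v"), category = "mWT")
  r0 <- simulate_composition(one, composition_config(inplane_sd = 0,
                                                     outplane_sd = 0,
                                                     weight_sd = 0,
                                                     free_water_sd = 0),
                             seed = 1)
  expect_equal(r0$lean_g[1], r0$lean_g[2])
  expect_equal(r0$total_water_g[1], r0$total_water_g[2])
})

test_that("category centroids are reproduced within scatter SEM", {
  # the generator projects each configured centroid onto the composition
  # plane, so the recoverable quantity is the centroid's in-plane coordinates
  # (plus the centroid itself up to its small off-plane component)
  mice <- data.frame(mouse_id = sprintf("m%03d", 1:300),
                     category = rep(c("mWT", "fWT", "fKO"), 100))
  cfg <- composition_config()
  rec <- simulate_composition(mice, cfg, seed = 10)
  p <- composition_proportions(rec)
  k <- plane_coefficients(cfg$phi_deg, cfg$psi_deg)
  tr <- plane_transform(p$lean_p, p$fat_p, p$specific_water_p, k)
  cen <- cfg$centroids
  ctr <- plane_transform(cen$lean_p, cen$fat_p, cen$water_p, k)
  sem3 <- 3 * cfg$inplane_sd / sqrt(100)
  for (cat in c("mWT", "fWT", "fKO")) {
    i <- p$category == cat
    j <- cen$category == cat
    expect_lt(abs(mean(tr$xp[i]) - ctr$xp[j]), sem3)
    expect_lt(abs(mean(tr$zp[i]) - ctr$zp[j]), sem3)
    # proportions agree with the configured centroid up to its off-plane part
    expect_lt(abs(mean(p$lean_p[i]) - cen$lean_p[j]), 0.002 + abs(ctr$yp[j]))
    expect_lt(abs(mean(p$fat_p[i]) - cen$fat_p[j]), 0.002 + abs(ctr$yp[j]))
  }
})
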