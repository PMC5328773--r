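test_that("QMR proportions normalize components to total body mass", {
  rec <- data.frame(mouse_id = "a", total_weight_g = 22.0, lean_g = 18.898,
                    fat_g = 1.628, total_water_g = 16.258, free_water_g = 0.154)
  p <- composition_proportions(rec)
  expect_equal(round(p$lean_p, 3), 0.859)
  expect_equal(round(p$fat_p, 3), 0.074)
  expect_equal(round(p$total_water_p, 3), 0.739)
  expect_equal(round(p$free_water_p, 3), 0.007)
  expect_equal(p$total_p, p$lean_p + p$fat_p + p$free_water_p)

  rec$fat_g <- 0
  p0 <- composition_proportions(rec)
  expect_equal(p0$fat_p, 0)
  rec$free_water_g <- rec$total_water_g
  expect_equal(composition_proportions(rec)$specific_water_p, 0)
})

test_that("hydration ratio reproduces the category-mean table", {
  expect_equal(round(hydration_ratio(0.739, 0.007, 0.859), 3), 0.852)
  expect_equal(round(hydration_ratio(0.722, 0.006, 0.821), 3), 0.872)
  expect_equal(hydration_ratio(0.5, 0.5, 0.8), 0)
})

test_that("category-mean component sums reproduce the printed totals", {
  means <- read.csv(system.file("extdata/composition_means.csv",
                                package = "bkcolony"))
  printed_total <- c(mWT = 0.941, mhet = 0.939, mKO = 0.938, fWT = 0.924,
                     fhet = 0.924, fKO = 0.935)
  total <- means$lean_p + means$fat_p + means$free_water_p
  expect_true(all(abs(total - printed_total[means$category]) <= 0.002))
})

test_that("linear fit matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4)
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$x_intercept, -0.5)
  expect_equal(f$r_squared, 1)

  f2 <- linear_fit(c(0, 2), c(1, 5))  # two points: exact interpolation
  expect_equal(f2$slope, 2)
  expect_equal(f2$r_squared, 1)

  set.seed(13)
  xn <- runif(50); yn <- 0.9 - 0.6 * xn + rnorm(50, 0, 0.05)
  fn <- linear_fit(xn, yn)
  X <- cbind(1, xn)
  beta <- solve(t(X) %*% X, t(X) %*% yn)
  expect_equal(fn$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fn$slope, beta[2], tolerance = 1e-10)
})

test_that("plane coefficients at (39, 21.5) match the printed transform", {
  k <- plane_coefficients(39, 21.5)
  printed <- c(alpha = 0.777, beta = 0.629, gamma = 0.930, delta = 0.285,
               epsilon = 0.231, zeta = 0.723, eta = 0.586, theta = 0.366)
  # the printed values are rounded/truncated to 3 decimals (theta = 0.36650
  # was truncated), so agreement is to within 6e-4
  expect_true(all(abs(k[names(printed)] - printed) < 6e-4))
  # coefficient identities
  expect_equal(k[["alpha"]]^2 + k[["beta"]]^2, 1, tolerance = 1e-12)
  expect_equal(k[["gamma"]]^2 + k[["theta"]]^2, 1, tolerance = 1e-12)
  expect_equal(k[["zeta"]]^2 + k[["eta"]]^2 + k[["theta"]]^2, 1,
               tolerance = 1e-12)
})

test_that("coefficient identities hold across the angle range", {
  for (phi in c(0, 15.3, 45, 89.9)) for (psi in c(-60, -21.5, 0, 21.5, 60)) {
    k <- plane_coefficients(phi, psi)
    expect_equal(k[["delta"]], k[["alpha"]] * k[["theta"]], tolerance = 1e-12)
    expect_equal(k[["epsilon"]], k[["beta"]] * k[["theta"]], tolerance = 1e-12)
    expect_equal(k[["zeta"]]^2 + k[["eta"]]^2 + k[["theta"]]^2, 1,
                 tolerance = 1e-12)
  }
})

test_that("transform at zero angles is the identity permutation", {
  k <- plane_coefficients(0, 0)
  tr <- plane_transform(lean = 0.8, fat = 0.1, water = 0.7, k)
  expect_equal(tr$xp, 0.8)
  expect_equal(tr$zp, 0.1)
  expect_equal(tr$yp, 0.7)
})

test_that("in-plane round trip is the identity to 1e-12", {
  k <- plane_coefficients(39, 21.5)
  set.seed(2)
  xp <- runif(25, 0.5, 1.5); zp <- runif(25, -0.3, 0.5)
  p <- plane_invert(xp, zp, k)
  back <- plane_transform(p$lean, p$fat, p$water, k)
  expect_equal(back$xp, xp, tolerance = 1e-12)
  expect_equal(back$zp, zp, tolerance = 1e-12)
  expect_equal(back$yp, rep(0, 25), tolerance = 1e-12)
  # full 3D round trip through the yp offset
  p3 <- plane_invert(xp, zp, k, yp = 0.05)
  back3 <- plane_transform(p3$lean, p3$fat, p3$water, k)
  expect_equal(back3$yp, rep(0.05, 25), tolerance = 1e-12)
})

test_that("plane fit inverts a forward construction exactly", {
  k <- plane_coefficients(39, 21.5)
  set.seed(4)
  pts <- plane_invert(runif(30, 0.8, 1.2), runif(30, -0.1, 0.3), k)
  fit <- fit_plane_rotation(pts$lean, pts$fat, pts$water)
  expect_equal(fit$phi, 39, tolerance = 1e-6)
  expect_equal(fit$psi, 21.5, tolerance = 1e-6)
  expect_lt(fit$residual_ss, 1e-10)

  # specific water identically zero: the water axis is the plane normal
  fit0 <- fit_plane_rotation(lean = runif(10, 0.7, 0.9),
                             fat = runif(10, 0.05, 0.15),
                             water = rep(0, 10))
  expect_equal(fit0$phi, 0, tolerance = 1e-8)
  expect_equal(fit0$psi, 0, tolerance = 1e-8)

  expect_error(fit_plane_rotation(c(1, 2, 3), c(2, 4, 6), c(3, 6, 9)),
               "degenerate")
})

test_that("plane fit agrees with the grid-search oracle on a noisy cloud", {
  k <- plane_coefficients(39, 21.5)
  set.seed(6)
  pts <- plane_invert(runif(20, 0.8, 1.2), runif(20, -0.1, 0.3), k,
                      yp = rnorm(20, 0, 0.01))
  fit <- fit_plane_rotation(pts$lean, pts$fat, pts$water)
  oracle <- plane_grid_search(pts$lean, pts$fat, pts$water, step = 0.01)
  expect_lt(abs(fit$residual_ss - oracle$objective), 1e-6)
  expect_lt(abs(fit$phi - oracle$phi), 0.02)
  expect_lt(abs(fit$psi - oracle$psi), 0.02)
})

test_that("fitted angles are invariant under relabeling and uniform scaling", {
  k <- plane_coefficients(30, 10)
  set.seed(9)
  pts <- plane_invert(runif(15, 0.5, 1.5), runif(15, -0.2, 0.4), k,
                      yp = rnorm(15, 0, 0.02))
  f1 <- fit_plane_rotation(pts$lean, pts$fat, pts$water)
  perm <- sample(15)
  f2 <- fit_plane_rotation(pts$lean[perm], pts$fat[perm], pts$water[perm])
  expect_equal(f2$phi, f1$phi)
  expect_equal(f2$residual_ss, f1$residual_ss)
  f3 <- fit_plane_rotation(3 * pts$lean, 3 * pts$fat, 3 * pts$water)
  expect_equal(f3$phi, f1$phi, tolerance = 1e-10)
  expect_equal(f3$psi, f1$psi, tolerance = 1e-10)
})

test_that("Holm stepdown adjustment follows the hand-worked procedure", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.2, 4)), rep(0.8, 4))
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1, 1))
})
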