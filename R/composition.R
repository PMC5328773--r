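#' Body-composition proportions from QMR measurements
#'
#' Normalizes each QMR component (lean, fat, total water, free water) to the
#' total body mass and derives specific water (total minus free; the water
#' residing in lean tissue) and the component total (lean + fat + free
#' water, which estimates total body weight up to undetectable substances
#' and systematic error).
#'
#' @param records QMR data frame (`total_weight_g`, `lean_g`, `fat_g`,
#'   `total_water_g`, `free_water_g`; identifier columns are carried
#'   through).
#' @return the input with columns `lean_p`, `fat_p`, `total_water_p`,
#'   `free_water_p`, `specific_water_p`, `total_p` appended.
#' @export
composition_proportions <- function(records) {
  stopifnot(all(records$total_weight_g > 0))
  records$lean_p <- records$lean_g / records$total_weight_g
  records$fat_p <- records$fat_g / records$total_weight_g
  records$total_water_p <- records$total_water_g / records$total_weight_g
  records$free_water_p <- records$free_water_g / records$total_weight_g
  records$specific_water_p <- records$total_water_p - records$free_water_p
  records$total_p <- records$lean_p + records$fat_p + records$free_water_p
  records
}

#' Hydration ratio
#'
#' (Total water - free water) / lean: the water content of the lean
#' compartment, ~0.85 in adult mice. Works on proportions or on gram masses
#' (the body-weight normalization cancels).
#'
#' @param total_water,free_water,lean component values (proportions or
#'   grams).
#' @return hydration ratio.
#' @examples
#' hydration_ratio(0.739, 0.007, 0.859) # 0.852
#' @export
hydration_ratio <- function(total_water, free_water, lean) {
  stopifnot(all(lean > 0))
  (total_water - free_water) / lean
}

#' Ordinary least-squares line with x-intercept
#'
#' A thin OLS wrapper reporting the quantities used for the composition
#' component fits: slope, y-intercept, x-intercept (-intercept/slope), and
#' r-squared.
#'
#' @param x,y numeric vectors (at least two distinct x values).
#' @return list with `slope`, `intercept`, `x_intercept`, `r_squared`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(unique(x)) >= 2)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  list(slope = unname(co[2]), intercept = unname(co[1]),
       x_intercept = unname(-co[1] / co[2]),
       r_squared = r2)
}

#' Coefficients of the two-angle lean-fat-water plane rotation
#'
#' Axis convention: x = lean proportion, y = specific water proportion,
#' z = fat proportion. A rotation about the fat (z) axis by phi mixes lean
#' and water into the new x' axis; a second rotation about the resulting x'
#' axis by psi tilts fat into z'. The eight coefficients are
#' alpha = cos(phi), beta = sin(phi), gamma = cos(psi), theta = sin(psi),
#' delta = alpha*theta, epsilon = beta*theta, zeta = alpha*gamma,
#' eta = beta*gamma, satisfying alpha^2 + beta^2 = 1, gamma^2 + theta^2 = 1,
#' and zeta^2 + eta^2 + theta^2 = 1. Both rotations preserve the origin.
#'
#' @param phi_deg,psi_deg rotation angles in degrees.
#' @return named numeric vector `alpha, beta, gamma, delta, epsilon, zeta,
#'   eta, theta`.
#' @examples
#' round(plane_coefficients(39, 21.5), 3)
#' @export
plane_coefficients <- function(phi_deg, psi_deg) {
  phi <- phi_deg * pi / 180
  psi <- psi_deg * pi / 180
  a <- cos(phi); b <- sin(phi); g <- cos(psi); th <- sin(psi)
  c(alpha = a, beta = b, gamma = g, delta = a * th, epsilon = b * th,
    zeta = a * g, eta = b * g, theta = th)
}

#' Rotated-plane coordinates and their in-plane inverse
#'
#' Forward transform of a lean-fat-water point:
#' `x' = alpha*lean + beta*water`, `z' = gamma*fat + delta*water -
#' epsilon*lean`, `y' = zeta*water - eta*lean - theta*fat` (the out-of-plane
#' coordinate). For points in the fitted plane (y' = 0) the inverse is
#' `lean = alpha*x' - epsilon*z'`, `fat = gamma*z'`,
#' `water = beta*x' + delta*z'`; `plane_invert()` additionally accepts a
#' `yp` offset along the unit plane normal so arbitrary 3D points round-trip.
#'
#' @param lean,fat,water lean, fat, and specific-water proportions
#'   (vectors).
#' @param fit a `plane_fit` object, or a coefficient vector from
#'   [plane_coefficients()].
#' @param xp,zp,yp rotated coordinates (yp defaults to 0: in-plane).
#' @return `plane_transform()`: data frame `xp`, `yp`, `zp`;
#'   `plane_invert()`: data frame `lean`, `fat`, `water`.
#' @export
plane_transform <- function(lean, fat, water, fit) {
  k <- plane_fit_coefs(fit)
  data.frame(xp = k["alpha"] * lean + k["beta"] * water,
             yp = k["zeta"] * water - k["eta"] * lean - k["theta"] * fat,
             zp = k["gamma"] * fat + k["delta"] * water - k["epsilon"] * lean,
             row.names = NULL)
}

#' @rdname plane_transform
#' @export
plane_invert <- function(xp, zp, fit, yp = 0) {
  k <- plane_fit_coefs(fit)
  # unit normal of the plane in (lean, water, fat) order: (-eta, zeta, -theta)
  data.frame(lean = k["alpha"] * xp - k["epsilon"] * zp - k["eta"] * yp,
             fat = k["gamma"] * zp - k["theta"] * yp,
             water = k["beta"] * xp + k["delta"] * zp + k["zeta"] * yp,
             row.names = NULL)
}

plane_fit_coefs <- function(fit) {
  if (inherits(fit, "plane_fit")) fit$coefficients else fit
}

#' Least-squares origin-through plane as a two-angle rotation
#'
#' Finds the angles (phi, psi) whose rotated y' axis minimizes the sum of
#' squared out-of-plane coordinates `sum(y'^2)` over the point cloud, i.e.
#' the best plane through the origin in lean-fat-water proportion space
#' restricted to the two-rotation parametrization. Because
#' `y' = zeta*water - eta*lean - theta*fat` with
#' `(eta, zeta, theta)` a unit vector, the minimizer is the smallest
#' principal direction of the origin second-moment matrix; the eigenvector is
#' converted to angles under the sign convention zeta > 0, phi in [0, 90),
#' psi in (-90, 90). Angles are scale-invariant: uniformly rescaling the
#' cloud leaves them unchanged.
#'
#' @param lean,fat,water point coordinates (at least 3 non-collinear
#'   points).
#' @return object of class `plane_fit`: `phi`, `psi` (degrees),
#'   `coefficients` (the eight transform coefficients), `residual_ss`.
#' @export
fit_plane_rotation <- function(lean, fat, water) {
  pts <- cbind(lean = lean, water = water, fat = fat)
  stopifnot(nrow(pts) >= 3)
  M <- crossprod(pts)  # origin moment matrix, not centered
  eg <- eigen(M, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values, 1))
    stop("degenerate (collinear) point cloud; plane is not identifiable",
         call. = FALSE)
  nv <- eg$vectors[, 3]            # smallest principal direction
  if (nv[2] < 0) nv <- -nv         # sign convention: zeta > 0
  zeta <- nv[2]; eta <- -nv[1]; theta <- -nv[3]
  phi <- atan2(eta, zeta) * 180 / pi
  psi <- asin(theta) * 180 / pi
  out <- list(phi = phi, psi = psi,
              coefficients = plane_coefficients(phi, psi),
              residual_ss = eg$values[3])
  class(out) <- "plane_fit"
  out
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("plane rotation: phi = %.2f deg, psi = %.2f deg, residual SS = %.3g\n",
              x$phi, x$psi, x$residual_ss))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Grid-search oracle for the plane rotation objective
#'
#' Exhaustive search of `sum(y'^2)` over an angle grid. Slow and simple by
#' design: it exists to cross-check [fit_plane_rotation()] independently of
#' the eigendecomposition route.
#'
#' @param lean,fat,water point coordinates.
#' @param step grid step in degrees.
#' @return list with `phi`, `psi`, `objective`.
#' @export
plane_grid_search <- function(lean, fat, water, step = 0.01) {
  search <- function(phis, psis, best) {
    for (phi in phis) for (psi in psis) {
      obj <- plane_objective(lean, fat, water, phi, psi)
      if (obj < best$objective) best <- list(phi = phi, psi = psi, objective = obj)
    }
    best
  }
  best <- search(seq(0, 89.5, by = 0.5), seq(-89.5, 89.5, by = 0.5),
                 list(phi = NA, psi = NA, objective = Inf))
  # refine both angles in stages around the running optimum; the final stage
  # walks the full requested step over a +/- 0.06 degree neighborhood
  for (s in c(0.05, step)) {
    halo <- 12 * s  # covers the previous stage's grid spacing with margin
    best <- search(seq(max(0, best$phi - halo), min(90 - step, best$phi + halo),
                       by = s),
                   seq(best$psi - halo, best$psi + halo, by = s), best)
  }
  best
}

plane_objective <- function(lean, fat, water, phi, psi) {
  k <- plane_coefficients(phi, psi)
  sum((k["zeta"] * water - k["eta"] * lean - k["theta"] * fat)^2)
}
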