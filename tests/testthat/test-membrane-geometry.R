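test_that("sphere closed forms: bending energy 8 pi kappa, volume 4/3 pi R^3", {
  sp <- sphere_shape(1, physical_params(kappa = 10))
  expect_equal(bending_energy(sp), 80 * pi, tolerance = 1e-4)
  expect_equal(enclosed_volume(sp), 4 * pi / 3, tolerance = 1e-4)
  ## scale invariance of the bending quadrature
  e1 <- bending_energy(sphere_shape(1))
  for (f in c(0.1, 0.5, 5, 10)) {
    ef <- bending_energy(sphere_shape(f))
    expect_lt(abs(ef / e1 - 1), 1e-6)
  }
  ## volume scales with R^3
  expect_equal(enclosed_volume(sphere_shape(5)), 4 * pi / 3 * 125,
               tolerance = 1e-4)
})

test_that("zero-neck limit is two tangent spheres with closed-form geometry", {
  s <- build_shape(shape_params(0, 0.3, 10))
  expect_equal(s$E_bend, 160 * pi)
  Req <- sqrt(10 / pi)
  expect_equal(s$V, 4 * pi / 3 * (0.3^1.5 + 0.7^1.5) * Req^3, tolerance = 1e-12)
  expect_equal(s$S_total, 40)
  ## quadrature agrees with the closed forms on the two-component profile
  expect_equal(bending_energy(s), 160 * pi, tolerance = 1e-4)
  expect_equal(enclosed_volume(s), s$V, tolerance = 1e-3)

  ## equal split at A_p = pi: two spheres of radius sqrt(1/2)
  s2 <- build_shape(shape_params(0, 0.5, pi))
  expect_equal(s2$R_lobes_um, rep(sqrt(0.5), 2), tolerance = 1e-12)
  expect_equal(s2$V, 2 * (4 * pi / 3) * 0.5^1.5, tolerance = 1e-12)
})

test_that("area constraint and energy bounds hold across the (w, a) plane", {
  ws <- seq(0, 0.57, length.out = 20)
  as <- seq(0.02, 0.5, length.out = 20)
  kappa <- 10
  for (w in ws) for (a in as) {
    if (!feasible_wa(w, a)) next
    s <- build_shape(shape_params(w, a, 10), n_profile = 60)
    expect_true(s$converged)
    expect_lt(abs(s$S_total / 40 - 1), 1e-5)
    expect_gt(s$V, 0)
    expect_gte(s$E_bend, 8 * pi * kappa - 1e-9)
    expect_lte(s$E_neck, s$E_bend + 1e-9)
  }
})

test_that("constrained minimum shape matches the profile-relaxation oracle", {
  ## frozen oracle values: relax_shape() on a 81-node tangent-angle meridian
  frozen <- list(
    list(w = 0.3,  a = 0.3, E = 432.13),
    list(w = 0.2,  a = 0.2, E = 451.35),
    list(w = 0.4,  a = 0.4, E = 405.83),
    list(w = 0.05, a = 0.1, E = 488.93),
    list(w = 0.1,  a = 0.3, E = 479.97))
  for (fz in frozen) {
    s <- build_shape(shape_params(fz$w, fz$a, 10), floor_r0 = FALSE)
    expect_lt(abs(s$E_bend / fz$E - 1), 0.05)
  }
  ## one live relaxation run
  rx <- relax_shape(shape_params(0.1, 0.3, 10))
  expect_lt(abs(rx$E_bend_family / rx$E_bend - 1), 0.05)
  expect_lt(rx$split_residual, 1e-3)
  expect_lt(rx$closure_residual, 1e-3)

  ## the (0.3, 0.3) shape: area exact, energy between the one-sphere
  ## (Willmore) and two-sphere limits, as required for a descending
  ## neck-opening landscape
  s <- build_shape(shape_params(0.3, 0.3, 10))
  expect_lt(abs(s$S_total / 40 - 1), 1e-5)
  expect_gt(s$E_bend, 80 * pi)
  expect_lt(s$E_bend, 160 * pi)
})

test_that("quadrature refines consistently with meridian resolution", {
  s1 <- build_shape(shape_params(0.3, 0.3, 10), n_profile = 400)
  s4 <- build_shape(shape_params(0.3, 0.3, 10), n_profile = 1600)
  expect_lt(abs(bending_energy(s1) / bending_energy(s4) - 1), 0.005)
  expect_lt(abs(enclosed_volume(s1) / enclosed_volume(s4) - 1), 0.001)
})

test_that("bending energy is invariant under uniform profile rescaling", {
  s <- build_shape(shape_params(0.3, 0.3, 10))
  e0 <- bending_energy(s)
  for (f in c(0.1, 2, 10)) {
    sc <- s
    sc$profile$r_um <- sc$profile$r_um * f
    sc$profile$z_um <- sc$profile$z_um * f
    expect_lt(abs(bending_energy(sc) / e0 - 1), 1e-6)
  }
})

test_that("neck bending energy is floored, bounded and monotone", {
  p10 <- physical_params()
  ## non-increasing in w at small w
  b001 <- neck_bending_energy(shape_params(0.01, 0.3, 10), p10)
  b02  <- neck_bending_energy(shape_params(0.2, 0.3, 10), p10)
  expect_gt(b001, b02)
  ## w = 0 is the R0-waist limit, finite and equal to the small-w floor value
  b0 <- neck_bending_energy(shape_params(0, 0.3, 10), p10)
  expect_true(is.finite(b0))
  expect_equal(b0, b001, tolerance = 1e-6)
  ## larger vesicle at fixed w: larger absolute neck circumference
  bA  <- neck_bending_energy(shape_params(0.1, 0.3, 10), p10)
  bA2 <- neck_bending_energy(shape_params(0.1, 0.3, 20), p10)
  expect_gt(bA2, bA)
})

test_that("toroidal collar bending integral matches independent quadrature", {
  for (pars in list(c(0.1, 0.05), c(0.3, 0.2), c(0.5, 0.08))) {
    rn <- pars[1]; rho <- pars[2]
    phi1 <- 0.9; phi2 <- 1.1
    closed <- endofuse:::.collar_bend(rn, rho, phi1, phi2)
    rc <- rn + rho
    num <- stats::integrate(function(f) {
      r <- rc - rho * cos(f)
      (cos(f) / r - 1 / rho)^2 * r
    }, -phi2, phi1, rel.tol = 1e-10)$value * pi * rho
    expect_lt(abs(closed / num - 1), 0.01)
  }
})

test_that("V(w) is continuous down to the two-sphere limit", {
  a <- 0.3
  v0 <- build_shape(shape_params(0, a, 10), floor_r0 = FALSE)$V
  ws <- c(0.1, 0.05, 0.02, 0.01, 0.005)
  vs <- vapply(ws, function(w)
    build_shape(shape_params(w, a, 10), floor_r0 = FALSE)$V, numeric(1))
  expect_lt(max(abs(diff(c(rev(vs), v0)))) / v0, 0.01)
  expect_lt(abs(vs[length(vs)] / v0 - 1), 0.005)
})

test_that("infeasible and invalid inputs fail with informative errors", {
  expect_error(shape_params(0.5, 0.05, 10), "neck radius|feasib|sqrt")
  expect_error(shape_params(-0.1, 0.3, 10), "w")
  expect_error(shape_params(0.1, 0.7, 10), "a")
  expect_error(shape_params(0.1, 0.3, -1), "A_p")
  expect_false(feasible_wa(0.5, 0.05))
  expect_true(feasible_wa(0.5, 0.2))
  ## open profile rejected
  s <- sphere_shape(1)
  s$profile <- s$profile[10:100, ]
  expect_error(bending_energy(s), "open profile")
  expect_error(enclosed_volume(s), "open profile")
})

test_that("shape export writes meridian CSV and JSON summary", {
  s <- build_shape(shape_params(0.3, 0.3, 10))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".json")
  write_shape_csv(s, f1)
  prof <- read.csv(f1)
  expect_named(prof, c("arclength_um", "r_um", "z_um", "component"))
  expect_gt(nrow(prof), 100)
  shape_json(s, f2)
  js <- jsonlite::read_json(f2)
  expect_equal(js$w, 0.3)
  expect_equal(js$S_total_um2, 40, tolerance = 1e-5)
  unlink(c(f1, f2))
})
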