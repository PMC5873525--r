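env <- air_environment()

test_that("air environment is internally consistent", {
  expect_equal(env$kinematic_viscosity,
               env$dynamic_viscosity / env$air_density,
               tolerance = 1e-6)
  expect_true(all(unlist(env[c("temperature", "pressure",
                               "dynamic_viscosity", "kinematic_viscosity",
                               "mean_free_path")]) > 0))
  expect_error(air_environment(temperature = -1))
  # overrides are honoured exactly
  e2 <- air_environment(dynamic_viscosity = 1.81e-5,
                        mean_free_path = 0.0665e-6)
  expect_identical(e2$dynamic_viscosity, 1.81e-5)
  expect_identical(e2$mean_free_path, 0.0665e-6)
})

test_that("slip correction matches the closed form and its limits", {
  # frozen oracle values (oracle_cc, lambda = 66.5 nm at 293.15 K)
  expect_equal(slip_correction(1e-6, env), 1.167195, tolerance = 1e-5)
  expect_equal(slip_correction(0.1e-6, env), 2.904469, tolerance = 1e-5)
  d <- 10^seq(-8, -4, length.out = 60)
  expect_equal(slip_correction(d, env), oracle_cc(d), tolerance = 1e-12)
  expect_true(all(slip_correction(d, env) >= 1))
  # no-slip limit
  expect_equal(slip_correction(1e-3, env), 1, tolerance = 1e-3)
  expect_error(slip_correction(0, env), "positive")
  expect_error(slip_correction(-1e-6, env), "positive")
})

test_that("settling velocity: oracle value, d^2 scaling, monotone", {
  expect_equal(settling_velocity(10e-6, env), 3.054595e-3,
               tolerance = 1e-5)
  da <- 10^seq(log10(0.05e-6), log10(50e-6), length.out = 80)
  expect_equal(settling_velocity(da, env), oracle_vt(da),
               tolerance = 1e-12)
  expect_true(all(diff(settling_velocity(da, env)) > 0))
  # quadratic scaling in the no-slip regime
  expect_equal(settling_velocity(40e-6, env) / settling_velocity(20e-6, env),
               4, tolerance = 0.01)
  expect_warning(settling_velocity(200e-6, env), "Stokes")
})

test_that("diffusion coefficient: oracle value, slip-enhanced scaling", {
  expect_equal(diffusion_coefficient(1e-6, env), 2.764078e-11,
               tolerance = 1e-5)
  d <- 10^seq(-8, -5, length.out = 50)
  expect_equal(diffusion_coefficient(d, env), oracle_diffusion(d),
               tolerance = 1e-12)
  expect_true(all(diff(diffusion_coefficient(d, env)) < 0))
  # halving d more than doubles D (slip enhancement)
  expect_gt(diffusion_coefficient(0.05e-6, env),
            2 * diffusion_coefficient(0.1e-6, env))
  # cold air diffuses less
  expect_lt(diffusion_coefficient(1e-6, air_environment(temperature = 100)),
            diffusion_coefficient(1e-6, env))
})

test_that("deposition velocity has the correct limits and lower bound", {
  s <- deposition_settings()
  # settling-dominated limit
  expect_equal(deposition_velocity(10e-6, env, s),
               settling_velocity(10e-6, env), tolerance = 1e-3)
  # diffusion-dominated limit
  expect_equal(deposition_velocity(0.01e-6, env, s),
               diffusion_coefficient(0.01e-6, env) /
                 s$boundary_layer_thickness,
               tolerance = 0.01)
  # v >= max(vt, D/db) on a log grid 0.01-20 um (closed-form inequality)
  da <- 10^seq(log10(0.01e-6), log10(20e-6), length.out = 200)
  v <- deposition_velocity(da, env, s)
  expect_true(all(v >= settling_velocity(da, env) - 1e-15))
  expect_true(all(v >= diffusion_coefficient(da, env) /
                    s$boundary_layer_thickness - 1e-15))
  # diffusion off reduces to settling exactly
  s_off <- deposition_settings(include_diffusion = FALSE)
  expect_identical(deposition_velocity(da, env, s_off),
                   settling_velocity(da, env))
})

test_that("gamma_mesh is the printed power law, strictly decreasing", {
  da <- 10^seq(log10(0.1e-6), log10(30e-6), length.out = 120)
  X <- da * oracle_vt(da) / env$kinematic_viscosity
  expect_equal(gamma_mesh(da, env), 5.95e-3 * X^(-0.439),
               tolerance = 1e-12)
  expect_true(all(diff(gamma_mesh(da, env)) < 0))
  # da giving X = 1e-3 evaluates to the frozen 0.1234574
  f <- function(d) d * oracle_vt(d) / env$kinematic_viscosity - 1e-3
  d_star <- uniroot(f, c(1e-7, 1e-4), tol = 1e-16)$root
  expect_equal(gamma_mesh(d_star, env), 0.1234574, tolerance = 1e-4)
  # gamma = 0.27 is crossed at X ~ 1.68e-4 (root of the printed formula)
  X_star <- (0.27 / 5.95e-3)^(-1 / 0.439)
  expect_equal(X_star, 1.68e-4, tolerance = 1e-2)
  # power-law scaling: X down tenfold multiplies gamma by 10^0.439
  d10 <- uniroot(function(d) d * oracle_vt(d) / env$kinematic_viscosity -
                   1e-4, c(1e-7, 1e-4), tol = 1e-16)$root
  expect_equal(gamma_mesh(d10, env) / gamma_mesh(d_star, env), 10^0.439,
               tolerance = 1e-6)
})

test_that("gamma_apply implements the three model variants", {
  da <- 10^seq(log10(0.05e-6), log10(30e-6), length.out = 1000)
  gm <- gamma_apply(da, env, gamma_model("mesh"))
  gh <- gamma_apply(da, env, gamma_model("hybrid"))
  ga <- gamma_apply(da, env, gamma_model("area"))
  # piecewise identity, exact to floating point
  expect_identical(gh, pmin(gm, 0.27))
  expect_identical(ga, rep(0.27, length(da)))
  # hybrid <= area everywhere; equality exactly where the power law >= 0.27
  expect_true(all(gh <= ga))
  expect_identical(gh == ga, gm >= 0.27)
  # small particles (power law large) are capped at 0.27
  expect_equal(gamma_apply(0.1e-6, env, gamma_model("hybrid")), 0.27)
  # at X = 1e-3 the power law (0.1234...) is below the cap and is kept
  d_star <- uniroot(function(d) d * oracle_vt(d) / env$kinematic_viscosity -
                      1e-3, c(1e-7, 1e-4), tol = 1e-16)$root
  expect_equal(gamma_apply(d_star, env, gamma_model("hybrid")), 0.1234574,
               tolerance = 1e-4)
  bad <- structure(list(variant = "frobnicate", open_area_ratio = 0.27),
                   class = "pas_gamma_model")
  expect_error(gamma_apply(1e-6, env, bad), "variant")
  expect_error(gamma_model(open_area_ratio = 0))
})

test_that("projected-aerodynamic conversion: identity, no-slip oracle,
           monotone in density, invertible", {
  ident <- material_properties(density = 1, volume_shape_factor = 1,
                               dynamic_shape_factor = 1)
  d <- c(0.3, 1, 5, 20)
  expect_equal(projected_to_aerodynamic(d, ident, env), d,
               tolerance = 1e-5)
  # no-slip closed form: 1.6^(-1/3) * sqrt(2800/1.4/1000)
  mat <- material_properties(2.8, 1.6, 1.4)
  expect_equal(projected_to_aerodynamic(1, mat, env, slip = FALSE),
               1.209136, tolerance = 1e-5)
  # slip shifts the sub-micron conversion away from the no-slip form
  expect_false(isTRUE(all.equal(projected_to_aerodynamic(0.1, mat, env),
                                0.1 * 1.209136, tolerance = 1e-3)))
  # monotone increasing in density at fixed d_pa (brute force over grid)
  rhos <- seq(0.5, 6, by = 0.5)
  das <- vapply(rhos, function(r) {
    projected_to_aerodynamic(2, material_properties(r, 1.6, 1.4), env)
  }, 0)
  expect_true(all(diff(das) > 0))
  # round trip with the inverse
  da <- projected_to_aerodynamic(d, mat, env)
  expect_equal(aerodynamic_to_projected(da, mat, env), d,
               tolerance = 1e-4)
})

test_that("particle mass is the shape-corrected sphere volume", {
  unit <- material_properties(density = 1, volume_shape_factor = 1)
  expect_equal(particle_mass(1, unit), pi / 6, tolerance = 1e-12)
  m16 <- material_properties(density = 1, volume_shape_factor = 1.6)
  expect_equal(particle_mass(1, m16), pi / 6 / 1.6, tolerance = 1e-12)
  expect_equal(particle_mass(2, unit) / particle_mass(1, unit), 8)
})
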