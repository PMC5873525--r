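# Aerosol microphysics: slip correction, settling, diffusion, deposition
# velocity, and the mesh-attenuation (gamma) models of a mesh-capped
# passive deposition sampler.
#
# Unit convention: physics-level functions take diameters in METRES and
# return SI quantities.  Interface-level functions (particle tables,
# quantification) use micrometres; they convert internally.

.kB <- 1.380649e-23        # Boltzmann constant, J/K
.g  <- 9.80665             # standard gravity, m/s^2
.M_AIR <- 0.0289647        # molar mass of dry air, kg/mol
.R_GAS <- 8.314462618      # J/(mol K)
.LAMBDA0 <- 66.5e-9        # air mean free path at 293.15 K, 101.325 kPa, m
.T0 <- 293.15              # reference temperature, K
.P0 <- 101325              # reference pressure, Pa
.SUTHERLAND <- 110.4       # Sutherland constant for air, K

#' Air environment for aerosol calculations
#'
#' Bundles the gas properties that the deposition model needs: dynamic and
#' kinematic viscosity, mean free path, and the unit-density reference used
#' in the definition of aerodynamic diameter.  Viscosity defaults to
#' Sutherland's law, the mean free path to 66.5 nm at 293.15 K / 101.325 kPa
#' scaled with temperature and pressure; both can be overridden to reproduce
#' any reference convention exactly.
#'
#' @param temperature air temperature, K.
#' @param pressure air pressure, Pa.
#' @param dynamic_viscosity dynamic viscosity of air, Pa s; `NULL` (default)
#'   computes Sutherland's law `1.458e-6 * T^1.5 / (T + 110.4)`.
#' @param mean_free_path gas mean free path, m; `NULL` (default) scales
#'   66.5 nm with temperature and pressure.
#' @param rho0_ref unit-density reference, kg/m^3 (1000 by definition of
#'   aerodynamic diameter; exposed for completeness only).
#' @return An object of class `pas_environment`: a list with fields
#'   `temperature`, `pressure`, `dynamic_viscosity`, `air_density`,
#'   `kinematic_viscosity`, `mean_free_path`, `rho0_ref`.
#' @examples
#' env <- air_environment()                 # 20 degC, 1 atm
#' cold <- air_environment(temperature = 263)  # an outdoor winter deployment
#' @export
air_environment <- function(temperature = 293.15, pressure = 101325,
                            dynamic_viscosity = NULL, mean_free_path = NULL,
                            rho0_ref = 1000) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature > 0, is.numeric(pressure), pressure > 0,
            rho0_ref > 0)
  mu <- if (is.null(dynamic_viscosity)) {
    1.458e-6 * temperature^1.5 / (temperature + .SUTHERLAND)
  } else {
    stopifnot(dynamic_viscosity > 0)
    dynamic_viscosity
  }
  lambda <- if (is.null(mean_free_path)) {
    # free-molecular scaling of the reference mean free path
    .LAMBDA0 * (temperature / .T0) * (.P0 / pressure) *
      (1 + .SUTHERLAND / .T0) / (1 + .SUTHERLAND / temperature)
  } else {
    stopifnot(mean_free_path > 0)
    mean_free_path
  }
  rho_air <- pressure * .M_AIR / (.R_GAS * temperature)
  structure(list(temperature = temperature,
                 pressure = pressure,
                 dynamic_viscosity = mu,
                 air_density = rho_air,
                 kinematic_viscosity = mu / rho_air,
                 mean_free_path = lambda,
                 rho0_ref = rho0_ref),
            class = "pas_environment")
}

#' Particle material properties
#'
#' Density and shape factors for the conversion from projected-area diameter
#' to volume-equivalent and aerodynamic diameter.  Defaults are the values
#' commonly applied to heterogeneous mineral dusts: volume shape factor 1.6,
#' dynamic shape factor 1.4.
#'
#' The volume convention is `V = (pi/6) * d_pa^3 / S_V`, so `S_V = 1`
#' recovers a sphere and the volume-equivalent diameter is
#' `d_ve = d_pa * S_V^(-1/3)`.
#'
#' @param density particle bulk density, g/cm^3.
#' @param volume_shape_factor dimensionless `S_V` (>= some positive value;
#'   1 = sphere).
#' @param dynamic_shape_factor dimensionless `chi` (>= 1; 1 = sphere).
#' @return Object of class `pas_material`.
#' @examples
#' mineral <- material_properties(density = 2.8)
#' concentrate <- material_properties(density = 3.75)
#' @export
material_properties <- function(density = 2.8, volume_shape_factor = 1.6,
                                dynamic_shape_factor = 1.4) {
  stopifnot(density > 0, volume_shape_factor > 0, dynamic_shape_factor >= 1)
  structure(list(density = density,
                 volume_shape_factor = volume_shape_factor,
                 dynamic_shape_factor = dynamic_shape_factor),
            class = "pas_material")
}

#' Mesh-attenuation model for a mesh-capped passive sampler
#'
#' The protective mesh cap attenuates the deposition velocity.  Three models
#' are supported:
#' \describe{
#'   \item{`"mesh"`}{the wind-tunnel power law
#'     `gamma = 5.95e-3 * (da * vt / nu)^(-0.439)` applied at all sizes;}
#'   \item{`"hybrid"`}{the power law capped at the mesh open-area ratio:
#'     `gamma = min(gamma_mesh, open_area_ratio)`;}
#'   \item{`"area"`}{the constant open-area ratio for every particle size.}
#' }
#' The default open-area ratio 0.27 is the open fraction of the standard
#' 150-um conical-hole mesh cap.
#'
#' @param variant one of `"mesh"`, `"hybrid"`, `"area"`.
#' @param open_area_ratio open fraction of the mesh cap, in (0, 1].
#' @return Object of class `pas_gamma_model`.
#' @export
gamma_model <- function(variant = c("hybrid", "mesh", "area"),
                        open_area_ratio = 0.27) {
  variant <- match.arg(variant)
  if (!is.numeric(open_area_ratio) || length(open_area_ratio) != 1L ||
      open_area_ratio <= 0 || open_area_ratio > 1) {
    stop("`open_area_ratio` must be a single value in (0, 1]",
         call. = FALSE)
  }
  structure(list(variant = variant, open_area_ratio = open_area_ratio),
            class = "pas_gamma_model")
}

#' Deposition-velocity settings
#'
#' The quiescent-air deposition velocity combines gravitational settling and
#' Brownian diffusion through a laminar boundary layer of thickness
#' `boundary_layer_thickness` (default 1 mm).  With `include_diffusion =
#' FALSE` the deposition velocity reduces to the terminal settling velocity,
#' which dominates for all supra-micrometre particles.
#'
#' @param boundary_layer_thickness boundary layer thickness, m.
#' @param include_diffusion logical; include the diffusive term.
#' @return Object of class `pas_deposition_settings`.
#' @export
deposition_settings <- function(boundary_layer_thickness = 1e-3,
                                include_diffusion = TRUE) {
  stopifnot(boundary_layer_thickness > 0,
            is.logical(include_diffusion), length(include_diffusion) == 1L)
  structure(list(boundary_layer_thickness = boundary_layer_thickness,
                 include_diffusion = include_diffusion),
            class = "pas_deposition_settings")
}

.check_diameter <- function(d, what = "d") {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", what),
         call. = FALSE)
  }
}

#' Cunningham slip correction factor
#'
#' Single-expression form `Cc = 1 + (lambda/d) * (2.514 + 0.800 *
#' exp(-0.55 d/lambda))`, with the mean free path taken from `env`.
#'
#' @param d particle diameter, m (vectorised).
#' @param env [air_environment()].
#' @return Dimensionless slip correction, >= 1.
#' @examples
#' slip_correction(1e-6, air_environment())   # ~1.17 at 20 degC
#' @export
slip_correction <- function(d, env = air_environment()) {
  .check_diameter(d)
  lambda <- env$mean_free_path
  1 + (lambda / d) * (2.514 + 0.800 * exp(-0.55 * d / lambda))
}

#' Terminal settling velocity of the aerodynamic-equivalent sphere
#'
#' Stokes settling with slip for a unit-density sphere of diameter `da`
#' (identical, by definition of aerodynamic diameter, to the true particle's
#' settling velocity).
#'
#' @param da aerodynamic diameter, m (vectorised).
#' @param env [air_environment()].
#' @return Settling velocity, m/s; strictly increasing in `da`.
#' @examples
#' settling_velocity(10e-6, air_environment())  # ~3.1e-3 m/s
#' @export
settling_velocity <- function(da, env = air_environment()) {
  .check_diameter(da, "da")
  if (any(da > 100e-6)) {
    warning("settling velocity outside Stokes validity (da > 100 um); ",
            "computed anyway", call. = FALSE)
  }
  env$rho0_ref * da^2 * .g * slip_correction(da, env) /
    (18 * env$dynamic_viscosity)
}

#' Brownian diffusion coefficient (Stokes-Einstein)
#'
#' @param d particle diameter, m (vectorised).
#' @param env [air_environment()].
#' @return Diffusion coefficient, m^2/s; strictly decreasing in `d`.
#' @export
diffusion_coefficient <- function(d, env = air_environment()) {
  .check_diameter(d)
  .kB * env$temperature * slip_correction(d, env) /
    (3 * pi * env$dynamic_viscosity * d)
}

#' Quiescent-air deposition velocity
#'
#' Combined settling + diffusion deposition velocity onto an upward-facing
#' surface under still air,
#' `v = vt / (1 - exp(-vt * delta_b / D))`,
#' which tends to `vt` for large particles and to `D/delta_b` for small
#' ones, and satisfies `v >= max(vt, D/delta_b)` everywhere.
#'
#' @param da aerodynamic diameter, m (vectorised).
#' @param env [air_environment()].
#' @param settings [deposition_settings()].
#' @return Deposition velocity, m/s.
#' @export
deposition_velocity <- function(da, env = air_environment(),
                                settings = deposition_settings()) {
  .check_diameter(da, "da")
  vt <- settling_velocity(da, env)
  if (!settings$include_diffusion) return(vt)
  db <- settings$boundary_layer_thickness
  D <- diffusion_coefficient(da, env)
  x <- vt * db / D
  # -expm1(-x) is accurate for small x; the x -> 0 limit is D/db
  v <- ifelse(x < 1e-12, D / db, vt / (-expm1(-x)))
  # exp underflow at huge x returns vt exactly, the analytic limit
  v
}

#' Mesh-factor power law
#'
#' The wind-tunnel mesh factor `gamma = 5.95e-3 * X^(-0.439)` with
#' `X = da * vt(da) / nu` the dimensionless settling parameter.  Strictly
#' decreasing in `da`.
#'
#' @param da aerodynamic diameter, m (vectorised).
#' @param env [air_environment()].
#' @return Dimensionless attenuation factor.
#' @export
gamma_mesh <- function(da, env = air_environment()) {
  .check_diameter(da, "da")
  X <- da * settling_velocity(da, env) / env$kinematic_viscosity
  5.95e-3 * X^(-0.439)
}

#' Apply a mesh-attenuation model
#'
#' @param da aerodynamic diameter, m (vectorised).
#' @param env [air_environment()].
#' @param model [gamma_model()].
#' @return Dimensionless gamma under the model's variant: the raw power law
#'   (`"mesh"`), its cap at the open-area ratio (`"hybrid"`), or the
#'   constant open-area ratio (`"area"`).
#' @export
gamma_apply <- function(da, env = air_environment(),
                        model = gamma_model()) {
  .check_diameter(da, "da")
  if (!inherits(model, "pas_gamma_model")) {
    stop("`model` must be a `pas_gamma_model` (see `gamma_model()`)",
         call. = FALSE)
  }
  switch(model$variant,
         mesh = gamma_mesh(da, env),
         hybrid = pmin(gamma_mesh(da, env), model$open_area_ratio),
         area = rep_len(model$open_area_ratio, length(da)),
         stop("unknown gamma model variant: ", model$variant, call. = FALSE))
}

#' Convert projected-area diameter to aerodynamic diameter
#'
#' Chain: projected-area diameter -> volume-equivalent diameter
#' `d_ve = d_pa * S_V^(-1/3)` -> aerodynamic diameter solving
#' `da^2 Cc(da) rho0 = d_ve^2 Cc(d_ve) rho_p / chi` by fixed-point
#' iteration (slip-corrected).  With `slip = FALSE` the closed form
#' `da = d_ve * sqrt(rho_p / (chi * rho0))` is returned.
#'
#' @param d_pa projected-area diameter, um (vectorised).
#' @param mat [material_properties()].
#' @param env [air_environment()].
#' @param slip logical; apply slip correction in the conversion.
#' @param tol convergence tolerance on `da`, um.
#' @param max_iter maximum fixed-point iterations.
#' @return Aerodynamic diameter, um.
#' @examples
#' projected_to_aerodynamic(1, material_properties(density = 2.8))
#' @export
projected_to_aerodynamic <- function(d_pa, mat = material_properties(),
                                     env = air_environment(), slip = TRUE,
                                     tol = 1e-6, max_iter = 100L) {
  .check_diameter(d_pa, "d_pa")
  d_ve <- d_pa * mat$volume_shape_factor^(-1 / 3)
  ratio <- (mat$density * 1000 / mat$dynamic_shape_factor) / env$rho0_ref
  if (!slip) return(d_ve * sqrt(ratio))
  target <- d_ve^2 * slip_correction(d_ve * 1e-6, env) * ratio  # um^2
  da <- d_ve * sqrt(ratio)
  for (i in seq_len(max_iter)) {
    da_new <- sqrt(target / slip_correction(da * 1e-6, env))
    if (max(abs(da_new - da)) < tol) return(da_new)
    da <- da_new
  }
  stop("aerodynamic-diameter iteration did not converge after ",
       max_iter, " iterations", call. = FALSE)
}

#' Convert aerodynamic diameter back to projected-area diameter
#'
#' Inverse of [projected_to_aerodynamic()]; used by the deposition
#' simulator to assign image-plane sizes to particles drawn on an
#' aerodynamic-diameter grid.
#'
#' @inheritParams projected_to_aerodynamic
#' @param da aerodynamic diameter, um (vectorised).
#' @return Projected-area diameter, um.
#' @export
aerodynamic_to_projected <- function(da, mat = material_properties(),
                                     env = air_environment(), slip = TRUE,
                                     tol = 1e-6, max_iter = 100L) {
  .check_diameter(da, "da")
  ratio <- (mat$density * 1000 / mat$dynamic_shape_factor) / env$rho0_ref
  if (!slip) return(da / sqrt(ratio) * mat$volume_shape_factor^(1 / 3))
  target <- da^2 * slip_correction(da * 1e-6, env) / ratio  # um^2 * Cc
  d_ve <- da / sqrt(ratio)
  for (i in seq_len(max_iter)) {
    d_new <- sqrt(target / slip_correction(d_ve * 1e-6, env))
    if (max(abs(d_new - d_ve)) < tol) {
      return(d_new * mat$volume_shape_factor^(1 / 3))
    }
    d_ve <- d_new
  }
  stop("volume-equivalent-diameter iteration did not converge after ",
       max_iter, " iterations", call. = FALSE)
}

#' Particle mass from projected-area diameter
#'
#' `m = rho_p * (pi/6) * d_pa^3 / S_V`.  With `d_pa` in um and density in
#' g/cm^3 the result is in picograms.
#'
#' @param d_pa projected-area diameter, um (vectorised).
#' @param mat [material_properties()].
#' @return Particle mass, pg.
#' @examples
#' particle_mass(1, material_properties(density = 1, volume_shape_factor = 1))
#' # 0.5236 pg: a unit-density 1-um sphere
#' @export
particle_mass <- function(d_pa, mat = material_properties()) {
  .check_diameter(d_pa, "d_pa")
  mat$density * (pi / 6) * d_pa^3 / mat$volume_shape_factor
}

#' @export
print.pas_environment <- function(x, ...) {
  cat(sprintf(paste0("<air environment>  T = %.2f K, P = %.0f Pa\n",
                     "  mu = %.4g Pa s, nu = %.4g m2/s, lambda = %.3g nm\n"),
              x$temperature, x$pressure, x$dynamic_viscosity,
              x$kinematic_viscosity, x$mean_free_path * 1e9))
  invisible(x)
}

#' @export
print.pas_gamma_model <- function(x, ...) {
  cat(sprintf("<gamma model> variant = %s, open area ratio = %.3g\n",
              x$variant, x$open_area_ratio))
  invisible(x)
}
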