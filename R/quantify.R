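# Mass-concentration quantification: inversion of the deposition flux per
# particle, size-selective fraction conventions (PM10 / PM2.5 / respirable),
# field-blank correction and normalised dM/dlogda size distributions.
#
# The mass balance inverted per particle is
#     C = 1/(A t) * sum_i  m_i / (gamma(da_i) * v_dep(da_i)),
# the unique dimensionally consistent inversion of a deposition flux
# gamma * v_dep * C collected on area A for time t.  The analyzed area is
# used directly: the deposition flux per unit area is uniform in
# expectation, so no rescaling by the fraction of the opening covered by
# the images is applied (that fraction is carried as metadata only).

#' Sampler deployment configuration
#'
#' Geometry and duration of one passive-sampler deployment.  Defaults match
#' an 8-h deployment analysed with 60 SEM fields of 450 um x 600 um,
#' covering 51% of the area projected by the mesh-cap opening.
#'
#' @param sampling_duration deployment time, s.
#' @param analyzed_area total analysed substrate area, m^2.
#' @param analyzed_fraction analysed area / projected opening area
#'   (metadata; not used in the concentration inversion).
#' @param substrate free-text substrate label.
#' @return Object of class `pas_sampler`.
#' @export
sampler_config <- function(sampling_duration = 8 * 3600,
                           analyzed_area = 60 * 450e-6 * 600e-6,
                           analyzed_fraction = 0.51,
                           substrate = "carbon tab") {
  stopifnot(sampling_duration > 0, analyzed_area > 0,
            analyzed_fraction > 0, analyzed_fraction <= 1)
  structure(list(sampling_duration = sampling_duration,
                 analyzed_area = analyzed_area,
                 analyzed_fraction = analyzed_fraction,
                 substrate = substrate),
            class = "pas_sampler")
}

#' Size-fraction sampling convention
#'
#' Collection-efficiency curve of a health-based size fraction as a
#' function of aerodynamic diameter:
#' \describe{
#'   \item{`"step"`}{ideal indicator, `E = 1` for `da <= cut`;}
#'   \item{`"lognormal_sigmoid"`}{sharp-impactor-like curve
#'     `E = 1 - Phi(ln(da/cut) / ln(gsd))` with `E(cut) = 0.5`;}
#'   \item{`"iso_respirable"`}{the shallow respirable convention
#'     `E = 0.5 (1 + exp(-0.06 da)) (1 - Phi(ln(da/4.25)/ln(1.5)))`,
#'     whose 50% cut-point falls at 4 um.}
#' }
#'
#' @param name `"PM10"`, `"PM2.5"` or `"respirable"`; sets the default cut
#'   diameter (10 / 2.5 / 4 um) and curve shape (sharp sigmoid for the
#'   impactor fractions, the respirable convention for `"respirable"`).
#' @param cut_diameter 50% cut-point, um (override).
#' @param curve_shape `"step"`, `"lognormal_sigmoid"` or `"iso_respirable"`.
#' @param gsd sigmoid sharpness as a geometric standard deviation; the
#'   default 1.1 gives a sharp impactor-like curve.
#' @return Object of class `pas_fraction`.
#' @examples
#' fraction_convention("PM2.5")
#' fraction_convention("PM10", curve_shape = "step")
#' @export
fraction_convention <- function(name = c("PM10", "PM2.5", "respirable"),
                                cut_diameter = NULL, curve_shape = NULL,
                                gsd = 1.1) {
  name <- match.arg(name)
  if (is.null(cut_diameter)) {
    cut_diameter <- switch(name, PM10 = 10, "PM2.5" = 2.5, respirable = 4)
  }
  if (is.null(curve_shape)) {
    curve_shape <- if (name == "respirable") "iso_respirable"
                   else "lognormal_sigmoid"
  }
  curve_shape <- match.arg(curve_shape,
                           c("step", "lognormal_sigmoid", "iso_respirable"))
  stopifnot(cut_diameter > 0, gsd > 1)
  structure(list(name = name, cut_diameter = cut_diameter,
                 curve_shape = curve_shape, gsd = gsd),
            class = "pas_fraction")
}

#' Collection efficiency of a fraction convention
#'
#' @param da aerodynamic diameter, um (vectorised).
#' @param conv [fraction_convention()].
#' @return Efficiency in `[0, 1]`, non-increasing in `da`.
#' @examples
#' fraction_efficiency(4, fraction_convention("respirable"))  # 0.50
#' @export
fraction_efficiency <- function(da, conv) {
  stopifnot(inherits(conv, "pas_fraction"))
  if (any(da < 0)) stop("`da` must be non-negative", call. = FALSE)
  switch(conv$curve_shape,
         step = as.numeric(da <= conv$cut_diameter),
         lognormal_sigmoid =
           1 - stats::pnorm(log(da / conv$cut_diameter) / log(conv$gsd)),
         iso_respirable =
           0.5 * (1 + exp(-0.06 * da)) *
             (1 - stats::pnorm(log(da / 4.25) / log(1.5))))
}

# Per-particle inferred airborne concentration contributions (mg/m^3).
# Shared by the total, fraction and size-distribution quantifiers.
.particle_contributions <- function(particles, model, sampler, mat, env,
                                    settings) {
  stopifnot(is.data.frame(particles))
  if (!"d_pa_um" %in% names(particles)) {
    if ("area_um2" %in% names(particles)) {
      particles$d_pa_um <- 2 * sqrt(particles$area_um2 / pi)
    } else {
      stop("particle table needs a `d_pa_um` or `area_um2` column",
           call. = FALSE)
    }
  }
  da <- projected_to_aerodynamic(particles$d_pa_um, mat, env)
  v <- deposition_velocity(da * 1e-6, env, settings)
  gam <- gamma_apply(da * 1e-6, env, model)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("non-positive deposition velocity encountered", call. = FALSE)
  }
  m_pg <- particle_mass(particles$d_pa_um, mat)
  # pg / (m/s * m^2 * s) = pg/m^3 = 1e-9 mg/m^3
  contrib <- m_pg / (gam * v * sampler$analyzed_area *
                       sampler$sampling_duration) * 1e-9
  data.frame(d_pa_um = particles$d_pa_um, da_um = da, mass_pg = m_pg,
             gamma = gam, v_dep_m_s = v, contribution_mg_m3 = contrib)
}

#' Total airborne mass concentration from a particle table
#'
#' Inverts the deposition flux particle by particle under the chosen
#' mesh-attenuation model and sums the inferred contributions.
#'
#' @param particles filtered particle table with a `d_pa_um` (or
#'   `area_um2`) column, e.g. from [filter_particles()].
#' @param model [gamma_model()].
#' @param sampler [sampler_config()].
#' @param mat [material_properties()].
#' @param env [air_environment()].
#' @param settings [deposition_settings()].
#' @return A list of class `pas_concentration`: `concentration_mg_m3`
#'   (total) and `particles`, the input table augmented with `da_um`,
#'   `mass_pg`, `gamma`, `v_dep_m_s` and `contribution_mg_m3` per particle
#'   for audit.
#' @export
concentration_total <- function(particles, model = gamma_model(),
                                sampler = sampler_config(),
                                mat = material_properties(),
                                env = air_environment(),
                                settings = deposition_settings()) {
  if (nrow(particles) == 0L) {
    warning("empty particle table: concentration is 0", call. = FALSE)
    return(structure(list(concentration_mg_m3 = 0,
                          particles = particles),
                     class = "pas_concentration"))
  }
  contrib <- .particle_contributions(particles, model, sampler, mat, env,
                                     settings)
  structure(list(concentration_mg_m3 = sum(contrib$contribution_mg_m3),
                 particles = contrib),
            class = "pas_concentration")
}

#' Fraction-weighted mass concentration
#'
#' Weights each particle's inferred concentration contribution by the
#' collection efficiency of a size-fraction convention at the particle's
#' aerodynamic diameter.
#'
#' @inheritParams concentration_total
#' @param conv [fraction_convention()].
#' @return Fraction concentration, mg/m^3 (a single number).
#' @export
fraction_concentration <- function(particles, conv, model = gamma_model(),
                                   sampler = sampler_config(),
                                   mat = material_properties(),
                                   env = air_environment(),
                                   settings = deposition_settings()) {
  if (nrow(particles) == 0L) {
    warning("empty particle table: concentration is 0", call. = FALSE)
    return(0)
  }
  contrib <- .particle_contributions(particles, model, sampler, mat, env,
                                     settings)
  sum(fraction_efficiency(contrib$da_um, conv) * contrib$contribution_mg_m3)
}

#' Field-blank correction
#'
#' Subtracts the mean of a group of field-blank concentrations from
#' measured values.  Negative corrected values are preserved unchanged:
#' truncating them would bias group means upward.
#'
#' @param values measured concentrations, mg/m^3 (vectorised).
#' @param blanks numeric vector of field-blank concentrations for the
#'   matching location group (>= 1 value).
#' @return Corrected values, mg/m^3.
#' @examples
#' blank_correct(c(0.5, 0.1), blanks = c(0.2, 0.2))  # 0.3, -0.1
#' @export
blank_correct <- function(values, blanks) {
  if (!is.numeric(blanks) || length(blanks) == 0L) {
    stop("blank group is empty: cannot compute a blank mean", call. = FALSE)
  }
  values - mean(blanks)
}

#' Binned size distribution with dM/dlogda normalisation
#'
#' Bins per-particle concentration contributions by aerodynamic diameter
#' and normalises each bin by its base-10 logarithmic width, so that
#' distributions measured with different bin grids are comparable.
#'
#' @inheritParams concentration_total
#' @param bin_edges strictly increasing positive aerodynamic-diameter bin
#'   edges, um.
#' @return Object of class `pas_size_distribution`: a data.frame with
#'   `bin_lo`, `bin_hi`, `dM` (mg/m^3 in the bin) and `dM_dlogda`
#'   (mg/m^3 per log10-decade), with attributes `underflow` / `overflow`
#'   holding any mass outside the grid (reported, not silently dropped).
#' @export
size_distribution <- function(particles, bin_edges, model = gamma_model(),
                              sampler = sampler_config(),
                              mat = material_properties(),
                              env = air_environment(),
                              settings = deposition_settings()) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2L,
            all(bin_edges > 0), all(diff(bin_edges) > 0))
  nb <- length(bin_edges) - 1L
  dM <- numeric(nb)
  under <- over <- 0
  if (nrow(particles) > 0L) {
    contrib <- .particle_contributions(particles, model, sampler, mat, env,
                                       settings)
    cut_idx <- findInterval(contrib$da_um, bin_edges,
                            rightmost.closed = TRUE)
    under <- sum(contrib$contribution_mg_m3[cut_idx == 0L])
    over <- sum(contrib$contribution_mg_m3[cut_idx > nb])
    inb <- cut_idx >= 1L & cut_idx <= nb
    if (any(inb)) {
      dM <- as.numeric(tapply(contrib$contribution_mg_m3[inb],
                              factor(cut_idx[inb], levels = seq_len(nb)),
                              sum, default = 0))
    }
    if (under > 0 || over > 0) {
      message(sprintf(
        "size_distribution: %.3g mg/m3 below and %.3g mg/m3 above the bin grid",
        under, over))
    }
  }
  widths <- diff(log10(bin_edges))
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1],
                    dM = dM,
                    dM_dlogda = dM / widths)
  attr(out, "underflow") <- under
  attr(out, "overflow") <- over
  class(out) <- c("pas_size_distribution", "data.frame")
  out
}

#' @export
print.pas_concentration <- function(x, ...) {
  cat(sprintf("<concentration> %.4g mg/m3 from %d particles\n",
              x$concentration_mg_m3, nrow(x$particles)))
  invisible(x)
}
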