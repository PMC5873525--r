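# Ground-truth-known generators for every pipeline stage: lognormal
# aerosol deposition onto the sampler substrate, micrograph rendering,
# and multi-occasion study tables with a known variance structure.

#' Aerosol specification
#'
#' A lognormal mass-size distribution in aerodynamic diameter, the
#' standard single-mode description of workplace mineral dust: mass median
#' aerodynamic diameter (MMAD), geometric standard deviation (GSD) and
#' total airborne mass concentration.
#'
#' @param mmad mass median aerodynamic diameter, um.
#' @param gsd geometric standard deviation (> 1).
#' @param total_mass_conc total mass concentration, mg/m^3.
#' @param material [material_properties()] of the particles.
#' @return Object of class `pas_aerosol`.
#' @export
aerosol_spec <- function(mmad = 5, gsd = 2, total_mass_conc = 1,
                         material = material_properties()) {
  stopifnot(mmad > 0, gsd > 1, total_mass_conc >= 0)
  structure(list(mmad = mmad, gsd = gsd,
                 total_mass_conc = total_mass_conc, material = material),
            class = "pas_aerosol")
}

#' Multi-occasion study specification
#'
#' Design of a simulated sampler-comparison study: a location x time grid
#' of measurement occasions, a fixed mean per occasion, a random
#' between-occasion effect and replicate noise.  Defaults mirror a
#' 4-location x 3-shift campaign with 10 passive-sampler replicates per
#' occasion and concentrations on the mg/m^3 scale of workplace dust.
#'
#' @param n_locations,n_times numbers of location and time levels.
#' @param replicates samplers per occasion.
#' @param occasion_means matrix (`n_locations` x `n_times`) of fixed mean
#'   concentrations, mg/m^3; default an additive location x time grid
#'   around 0.5 mg/m^3.
#' @param var_between between-occasion variance, (mg/m^3)^2.
#' @param var_within within-occasion (replicate) variance, (mg/m^3)^2.
#' @return Object of class `pas_study_spec`.
#' @export
study_spec <- function(n_locations = 4L, n_times = 3L, replicates = 10L,
                       occasion_means = NULL, var_between = 0.045,
                       var_within = 0.045) {
  stopifnot(n_locations >= 1, n_times >= 1, replicates >= 1,
            var_between >= 0, var_within >= 0)
  if (is.null(occasion_means)) {
    loc_eff <- seq(-0.2, 0.4, length.out = n_locations)
    time_eff <- seq(-0.1, 0.1, length.out = n_times)
    occasion_means <- outer(loc_eff, time_eff, `+`) + 0.5
  }
  occasion_means <- as.matrix(occasion_means)
  stopifnot(nrow(occasion_means) == n_locations,
            ncol(occasion_means) == n_times)
  structure(list(n_locations = as.integer(n_locations),
                 n_times = as.integer(n_times),
                 replicates = as.integer(replicates),
                 occasion_means = occasion_means,
                 var_between = var_between, var_within = var_within),
            class = "pas_study_spec")
}

#' Simulate particle deposition onto the analysed substrate area
#'
#' Forward model of passive deposition sampling.  The aerosol's lognormal
#' mass distribution is discretised on a log-spaced aerodynamic-diameter
#' grid; the number concentration per bin follows from the per-particle
#' mass (Hatch-Choate in discrete form: `N_j = C_mass,j / m(da_j)`); the
#' expected deposit on the analysed area is
#' `N_j * gamma(da_j) * v_dep(da_j) * A * t`, realised as Poisson counts
#' with uniform positions; the image-plane projected-area diameter is the
#' inverse of the aerodynamic conversion.
#'
#' @param aerosol [aerosol_spec()].
#' @param model [gamma_model()] under which deposition is simulated.
#' @param sampler [sampler_config()].
#' @param env [air_environment()].
#' @param settings [deposition_settings()].
#' @param calib [image_calibration()] used to lay particles out on image
#'   fields (`analyzed_area / field area` images).
#' @param seed integer seed; fixed seed gives an identical table.
#' @param n_bins number of log-spaced diameter bins.
#' @param da_range aerodynamic-diameter range covered, um; mass outside
#'   is not deposited and reported in the ground truth.
#' @param max_expected_count guard: refuse if the expected total particle
#'   count exceeds this.
#' @return A particle table (`image_id`, `d_pa_um`, `da_um`, `area_um2`,
#'   `x_um`, `y_um`) with attribute `"truth"`: a list with the generating
#'   concentration, the concentration recoverable on the bin grid
#'   (`recoverable_mass_conc`), its Poisson standard error
#'   (`concentration_se`), expected counts per bin and the bin grid.
#' @export
simulate_deposition <- function(aerosol, model = gamma_model(),
                                sampler = sampler_config(),
                                env = air_environment(),
                                settings = deposition_settings(),
                                calib = image_calibration(),
                                seed = NULL, n_bins = 80L,
                                da_range = c(0.2, 50),
                                max_expected_count = 1e7) {
  stopifnot(inherits(aerosol, "pas_aerosol"), n_bins >= 2L,
            length(da_range) == 2L, da_range[1] > 0,
            da_range[2] > da_range[1])
  A <- sampler$analyzed_area; t <- sampler$sampling_duration
  mat <- aerosol$material
  empty <- data.frame(image_id = integer(0), d_pa_um = numeric(0),
                      da_um = numeric(0), area_um2 = numeric(0),
                      x_um = numeric(0), y_um = numeric(0))
  edges <- exp(seq(log(da_range[1]), log(da_range[2]),
                   length.out = n_bins + 1L))
  mids <- sqrt(edges[-1] * edges[-length(edges)])
  # lognormal mass fraction in each bin
  mass_frac <- diff(stats::plnorm(edges, log(aerosol$mmad),
                                  log(aerosol$gsd)))
  c_mass <- aerosol$total_mass_conc * mass_frac           # mg/m^3 per bin
  d_pa <- if (aerosol$total_mass_conc > 0) {
    aerodynamic_to_projected(mids, mat, env)
  } else {
    mids
  }
  m_pg <- particle_mass(d_pa, mat)                        # pg
  n_conc <- c_mass / (m_pg * 1e-9)                        # particles / m^3
  v <- deposition_velocity(mids * 1e-6, env, settings)
  gam <- gamma_apply(mids * 1e-6, env, model)
  expected <- n_conc * gam * v * A * t
  if (sum(expected) > max_expected_count) {
    stop(sprintf("expected particle count %.3g exceeds the guard (%.3g)",
                 sum(expected), max_expected_count), call. = FALSE)
  }
  # per-particle inferred concentration and the Poisson error budget
  contrib <- m_pg / (gam * v * A * t) * 1e-9              # mg/m^3 each
  truth <- list(total_mass_conc = aerosol$total_mass_conc,
                recoverable_mass_conc = sum(expected * contrib),
                concentration_se = sqrt(sum(expected * contrib^2)),
                expected_counts = expected,
                bin_edges = edges, bin_mid_da = mids,
                mass_fraction_in_range = sum(mass_frac))
  if (aerosol$total_mass_conc == 0) {
    attr(empty, "truth") <- truth
    return(empty)
  }
  n_images <- max(1L, as.integer(round(
    A / (calib$image_width * calib$image_height * 1e-12))))
  tab <- .with_seed(seed, {
    counts <- stats::rpois(length(expected), expected)
    n <- sum(counts)
    if (n == 0L) {
      empty
    } else {
      bin <- rep(seq_along(counts), counts)
      data.frame(image_id = sample.int(n_images, n, replace = TRUE),
                 d_pa_um = d_pa[bin],
                 da_um = mids[bin],
                 area_um2 = pi / 4 * d_pa[bin]^2,
                 x_um = stats::runif(n, 0, calib$image_width),
                 y_um = stats::runif(n, 0, calib$image_height))
    }
  })
  tab <- tab[order(tab$image_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "truth") <- truth
  tab
}

#' Render a particle table as a synthetic micrograph
#'
#' Draws each particle as a filled disc of matching projected area
#' (foreground level 200 on background 20 by default), clips at the image
#' border, and adds Gaussian read noise.  Emulates a backscatter SEM view
#' of bright mineral particles on a dark substrate; it does not emulate
#' charging, focus or astigmatism artefacts.
#'
#' @param particles data.frame with `x_um`, `y_um` and `d_pa_um` (or
#'   `area_um2`) columns.
#' @param calib [image_calibration()].
#' @param noise_sd Gaussian noise standard deviation, gray levels.
#' @param seed integer seed for the noise.
#' @param foreground,background gray levels (0-255).
#' @return Integer matrix (`calib$ny` x `calib$nx`), levels 0-255.
#' @export
render_image <- function(particles, calib = image_calibration(),
                         noise_sd = 5, seed = NULL,
                         foreground = 200L, background = 20L) {
  stopifnot(noise_sd >= 0, foreground > background)
  ny <- calib$ny; nx <- calib$nx; ppm <- calib$pixels_per_micron
  img <- matrix(as.numeric(background), ny, nx)
  if (nrow(particles) > 0L) {
    if (!"d_pa_um" %in% names(particles)) {
      particles$d_pa_um <- 2 * sqrt(particles$area_um2 / pi)
    }
    for (i in seq_len(nrow(particles))) {
      # "matching projected area": paint the round(area_px) pixels nearest
      # the centre, so the rasterised area equals the particle's area to
      # rounding (naive centre-in-circle tests carry Gauss-circle errors
      # of several pixels).  Clipping at the border truncates the disc.
      n_px <- round(pi / 4 * particles$d_pa_um[i]^2 * ppm^2)
      if (n_px < 1) next
      r_px <- particles$d_pa_um[i] / 2 * ppm
      cx <- particles$x_um[i] * ppm   # in pixel units, origin at corner
      cy <- particles$y_um[i] * ppm
      pad <- ceiling(r_px) + 2L
      xs <- max(1L, floor(cx) - pad):min(nx, ceiling(cx) + pad)
      ys <- max(1L, floor(cy) - pad):min(ny, ceiling(cy) + pad)
      # pixel centre of column j is at j - 0.5
      d2 <- outer((ys - 0.5 - cy)^2, (xs - 0.5 - cx)^2, `+`)
      # candidates stay within a dilated disc so border particles clip to
      # a truncated disc rather than smearing along the border
      cand <- which(d2 <= (r_px + 1)^2)
      ord <- cand[order(d2[cand])]  # ties broken by index: deterministic
      take <- ord[seq_len(min(n_px, length(ord)))]
      ridx <- ys[((take - 1L) %% length(ys)) + 1L]
      cidx <- xs[((take - 1L) %/% length(ys)) + 1L]
      img[cbind(ridx, cidx)] <- foreground
    }
  }
  img <- .with_seed(seed, {
    img + if (noise_sd > 0) stats::rnorm(length(img), 0, noise_sd) else 0
  })
  img <- round(img)
  img[img < 0] <- 0; img[img > 255] <- 255
  mode(img) <- "integer"
  img
}

#' Simulate a multi-occasion study table
#'
#' `value = occasion fixed mean + N(0, var_between) occasion effect +
#' N(0, var_within) replicate noise`, matching the variance-component
#' model under which the ICC is defined.
#'
#' @param spec [study_spec()].
#' @param seed integer seed.
#' @param device device label stored in the table.
#' @return Long data.frame with columns `location`, `time`, `occasion`,
#'   `device`, `replicate`, `value`, and the true ICC
#'   `var_between / (var_between + var_within)` as attribute `"true_icc"`.
#' @export
simulate_study <- function(spec = study_spec(), seed = NULL,
                           device = "UNC") {
  stopifnot(inherits(spec, "pas_study_spec"))
  locs <- paste0("L", seq_len(spec$n_locations))
  times <- paste0("T", seq_len(spec$n_times))
  grid <- expand.grid(location = locs, time = times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  .with_seed(seed, {
    occ_eff <- stats::rnorm(nrow(grid), 0, sqrt(spec$var_between))
    rows <- lapply(seq_len(nrow(grid)), function(k) {
      mu <- spec$occasion_means[match(grid$location[k], locs),
                                match(grid$time[k], times)]
      data.frame(location = grid$location[k], time = grid$time[k],
                 occasion = paste(grid$location[k], grid$time[k], sep = ":"),
                 device = device,
                 replicate = seq_len(spec$replicates),
                 value = mu + occ_eff[k] +
                   stats::rnorm(spec$replicates, 0, sqrt(spec$var_within)))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    tot <- spec$var_between + spec$var_within
    attr(out, "true_icc") <- if (tot > 0) spec$var_between / tot else 0
    out
  })
}
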