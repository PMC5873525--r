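# Run configuration: one human-editable JSON mapping that carries every
# tunable of the pipeline (calibration, sampler geometry, per-location
# material and air environment, gamma model, fraction conventions, filter
# rules, blank grouping, seed).  All physical constants are overridable so
# any reference convention can be reproduced exactly.

#' Default run configuration
#'
#' Builds the nested configuration list used by the command-line entry
#' points.  Location labels map to a material/environment pair and to a
#' blank group, so one config can describe a campaign where, say, three
#' locations share a density and a blank-mean while a fourth (dustier or
#' mineralogically different) gets its own.
#'
#' @param locations named list: label -> list(density, temperature,
#'   blank_group).
#' @param blank_groups named list: group label -> numeric vector of field
#'   blank concentrations per fraction (named PM10/PM2.5/respirable),
#'   mg/m^3.
#' @param model gamma model variant (`"mesh"`, `"hybrid"`, `"area"`).
#' @param seed integer default seed for the stochastic commands.
#' @return Nested list of class `pas_config`.
#' @export
run_config <- function(locations = list(
                         crushing = list(density = 2.8, temperature = 263,
                                         blank_group = "main"),
                         drive = list(density = 2.8, temperature = 287,
                                      blank_group = "drive"),
                         concentrator = list(density = 2.8,
                                             temperature = 292,
                                             blank_group = "main"),
                         terminal = list(density = 3.75, temperature = 277,
                                         blank_group = "main")),
                       blank_groups = list(
                         main = list(PM10 = 0, PM2.5 = 0, respirable = 0),
                         drive = list(PM10 = 0, PM2.5 = 0, respirable = 0)),
                       model = "area", seed = 1L) {
  cfg <- list(
    calibration = list(pixels_per_micron = 1.71, image_width = 450,
                       image_height = 600),
    sampler = list(sampling_duration = 8 * 3600,
                   analyzed_area = 60 * 450e-6 * 600e-6,
                   analyzed_fraction = 0.51, substrate = "carbon tab"),
    material = list(volume_shape_factor = 1.6, dynamic_shape_factor = 1.4),
    environment = list(pressure = 101325),
    deposition = list(boundary_layer_thickness = 1e-3,
                      include_diffusion = TRUE),
    model = list(variant = model, open_area_ratio = 0.27),
    fractions = list(
      PM10 = list(cut_diameter = 10, curve_shape = "lognormal_sigmoid",
                  gsd = 1.1),
      PM2.5 = list(cut_diameter = 2.5, curve_shape = "lognormal_sigmoid",
                   gsd = 1.1),
      respirable = list(cut_diameter = 4, curve_shape = "iso_respirable",
                        gsd = 1.5)),
    filter = list(min_area = NULL, max_area = 10000, exclude_edge = TRUE),
    threshold = list(method = "renyi_entropy", alpha = 1,
                     refine = FALSE),
    locations = locations,
    blank_groups = blank_groups,
    seed = seed)
  class(cfg) <- "pas_config"
  cfg
}

#' Read / write a run configuration
#'
#' Configurations are stored as pretty-printed JSON and round-trip
#' losslessly.
#'
#' @param path file path.
#' @return `read_run_config()` returns a `pas_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    .pas_config_error("config file not found: ", path)
  }
  cfg <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE),
    error = function(e) .pas_config_error("malformed config JSON: ",
                                          conditionMessage(e)))
  class(cfg) <- "pas_config"
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list from [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# materialise package objects from a config, for one location label
.cfg_objects <- function(cfg, location = NULL) {
  loc <- if (!is.null(location)) {
    if (is.null(cfg$locations[[location]])) {
      .pas_config_error("unknown location label: ", location)
    }
    cfg$locations[[location]]
  } else {
    list(density = 2.8, temperature = 293.15, blank_group = NULL)
  }
  env <- air_environment(temperature = loc$temperature %||% 293.15,
                         pressure = cfg$environment$pressure %||% 101325)
  mat <- material_properties(
    density = loc$density %||% 2.8,
    volume_shape_factor = cfg$material$volume_shape_factor %||% 1.6,
    dynamic_shape_factor = cfg$material$dynamic_shape_factor %||% 1.4)
  calib <- image_calibration(cfg$calibration$pixels_per_micron %||% 1.71,
                             cfg$calibration$image_width %||% 450,
                             cfg$calibration$image_height %||% 600)
  sampler <- sampler_config(cfg$sampler$sampling_duration %||% (8 * 3600),
                            cfg$sampler$analyzed_area %||%
                              (60 * 450e-6 * 600e-6),
                            cfg$sampler$analyzed_fraction %||% 0.51,
                            cfg$sampler$substrate %||% "carbon tab")
  model <- gamma_model(cfg$model$variant %||% "area",
                       cfg$model$open_area_ratio %||% 0.27)
  settings <- deposition_settings(
    cfg$deposition$boundary_layer_thickness %||% 1e-3,
    cfg$deposition$include_diffusion %||% TRUE)
  rules <- filter_rules(cfg$filter$min_area,
                        cfg$filter$max_area %||% 10000,
                        cfg$filter$exclude_edge %||% TRUE, calib)
  fractions <- lapply(names(cfg$fractions), function(nm) {
    f <- cfg$fractions[[nm]]
    fraction_convention(nm, f$cut_diameter, f$curve_shape,
                        f$gsd %||% 1.1)
  })
  names(fractions) <- names(cfg$fractions)
  list(env = env, mat = mat, calib = calib, sampler = sampler,
       model = model, settings = settings, rules = rules,
       fractions = fractions, blank_group = loc$blank_group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
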