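# Segmentation of calibrated grayscale micrographs into particle tables:
# histogram thresholding (Renyi entropy / triangle), 8-connected component
# labelling, and the exclusion rules used for mesh-capped passive samplers
# (one-pixel minimum area, mesh-cap maximum area, edge exclusion).
#
# Images are integer matrices, rows = y (top to bottom), columns = x.

#' Image calibration
#'
#' Pixel scale and physical field size of a micrograph.  The study defaults
#' correspond to a x500 SEM field: 1.71 px/um over 450 um x 600 um
#' (the x3000 tiles use 14.3 px/um).
#'
#' @param pixels_per_micron pixel scale, px/um.
#' @param image_width physical field width (x), um.
#' @param image_height physical field height (y), um.
#' @return Object of class `pas_calibration` with the derived fields
#'   `pixel_area` (um^2 per pixel) and `nx`, `ny` (pixel dimensions).
#' @examples
#' image_calibration()                       # x500 field
#' image_calibration(14.3, 150, 200)         # a high-magnification tile
#' @export
image_calibration <- function(pixels_per_micron = 1.71,
                              image_width = 450, image_height = 600) {
  stopifnot(pixels_per_micron > 0, image_width > 0, image_height > 0)
  structure(list(pixels_per_micron = pixels_per_micron,
                 image_width = image_width,
                 image_height = image_height,
                 pixel_area = pixels_per_micron^(-2),
                 nx = as.integer(round(image_width * pixels_per_micron)),
                 ny = as.integer(round(image_height * pixels_per_micron))),
            class = "pas_calibration")
}

#' Particle filter rules
#'
#' The three exclusion rules applied to a segmented particle table:
#' a minimum area equal to one pixel of the calibration (objects smaller
#' than one pixel cannot be resolved), a maximum area of 10000 um^2
#' (anything larger cannot have passed the mesh cap and is an artefact),
#' and exclusion of particles touching the image border (their area is
#' truncated and unknown).
#'
#' @param min_area minimum retained area, um^2.  `NULL` (default) uses one
#'   pixel of `calib` (0.34 um^2 at 1.71 px/um).
#' @param max_area maximum retained area, um^2.
#' @param exclude_edge logical; drop border-touching particles.
#' @param calib [image_calibration()] used for the one-pixel default.
#' @return Object of class `pas_filter_rules`.
#' @export
filter_rules <- function(min_area = NULL, max_area = 10000,
                         exclude_edge = TRUE,
                         calib = image_calibration()) {
  if (is.null(min_area)) min_area <- calib$pixel_area
  stopifnot(min_area > 0, max_area > min_area,
            is.logical(exclude_edge), length(exclude_edge) == 1L)
  structure(list(min_area = min_area, max_area = max_area,
                 exclude_edge = exclude_edge),
            class = "pas_filter_rules")
}

# histogram over integer levels 0..nlev-1
.image_histogram <- function(image, nlev) {
  tabulate(as.integer(image) + 1L, nbins = nlev)
}

.threshold_renyi <- function(h, alpha = 1) {
  # maximise the sum of the Renyi entropies of the two classes split at t
  # (alpha -> 1 gives the Shannon / maximum-entropy criterion).
  p <- h / sum(h)
  nz <- which(p > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  if (lo == hi) return(NA_integer_)
  P <- cumsum(p)
  best <- -Inf; best_t <- lo
  for (t in lo:(hi - 1L)) {
    w0 <- P[t]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    p0 <- p[1:t] / w0
    p1 <- p[(t + 1L):length(p)] / w1
    if (abs(alpha - 1) < 1e-9) {
      H0 <- -sum(ifelse(p0 > 0, p0 * log(p0), 0))
      H1 <- -sum(ifelse(p1 > 0, p1 * log(p1), 0))
    } else {
      H0 <- log(sum(p0^alpha)) / (1 - alpha)
      H1 <- log(sum(p1^alpha)) / (1 - alpha)
    }
    if (H0 + H1 > best) { best <- H0 + H1; best_t <- t }
  }
  best_t - 1L  # histogram bin 1 is level 0
}

.threshold_triangle <- function(h) {
  # maximise the distance from the histogram to the chord joining the peak
  # to the far end of the longer tail
  nz <- which(h > 0)
  if (length(nz) < 2L) return(NA_integer_)
  peak <- which.max(h)
  lo <- nz[1]; hi <- nz[length(nz)]
  # search on the longer side of the peak
  if ((hi - peak) >= (peak - lo)) { a <- peak; b <- hi } else { a <- lo; b <- peak }
  if (a == b) return(NA_integer_)
  # chord from (peak, h[peak]) to (tail end, h[tail end])
  x1 <- peak; y1 <- h[peak]; x2 <- if (a == peak) b else a; y2 <- h[x2]
  xs <- a:b
  num <- abs((y2 - y1) * xs - (x2 - x1) * h[xs] + x2 * y1 - y2 * x1)
  t <- xs[which.max(num)]
  t - 1L
}

#' Threshold a grayscale image
#'
#' Histogram thresholding with the Renyi-entropy criterion (the default;
#' the order-`alpha` entropy of the two classes is maximised, `alpha = 1`
#' giving the classic maximum-entropy method) or the triangle method
#' (maximum histogram-to-chord distance on the longer tail of the peak).
#' Foreground is the bright side: pixels strictly above the threshold.
#'
#' Both histogram criteria place the threshold near the foot of the
#' background peak, which on images with uncorrelated read noise admits
#' stray background pixels a few sigma above the mean.  The optional
#' `refine` pass reassigns each initial foreground pixel to the class
#' whose mean intensity it is closer to (one ISODATA-style step),
#' removing isolated noise pixels and noise attached to particle rims
#' while leaving true particle pixels — far from the class midpoint —
#' untouched.
#'
#' @param image integer matrix, levels `0 .. 2^bit_depth - 1`.
#' @param method `"renyi_entropy"` or `"triangle"`.
#' @param alpha Renyi entropy order (ignored for triangle).
#' @param bit_depth 8 or 16.
#' @param refine logical; apply the class-mean refinement pass.
#' @return Logical matrix of the same shape, `TRUE` = particle pixel, with
#'   the integer threshold attached as attribute `"threshold"` (and, when
#'   refined, `"refined_threshold"`, the class-mean midpoint).  A constant
#'   image has no defined threshold: an empty mask is returned with a
#'   warning.
#' @export
threshold_image <- function(image, method = c("renyi_entropy", "triangle"),
                            alpha = 1, bit_depth = 8L, refine = FALSE) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), bit_depth %in% c(8L, 16L))
  nlev <- 2L^bit_depth
  if (any(image < 0 | image > nlev - 1L)) {
    stop("image values outside 0..", nlev - 1L, call. = FALSE)
  }
  h <- .image_histogram(image, nlev)
  t <- switch(method,
              renyi_entropy = .threshold_renyi(h, alpha),
              triangle = .threshold_triangle(h))
  if (is.na(t)) {
    warning("constant image: no threshold defined, returning empty mask",
            call. = FALSE)
    mask <- matrix(FALSE, nrow(image), ncol(image))
    attr(mask, "threshold") <- NA_integer_
    return(mask)
  }
  mask <- image > t
  attr(mask, "threshold") <- as.integer(t)
  if (refine && any(mask) && !all(mask)) {
    mid <- (mean(image[mask]) + mean(image[!mask])) / 2
    mask2 <- image > mid
    attr(mask2, "threshold") <- as.integer(t)
    attr(mask2, "refined_threshold") <- mid
    return(mask2)
  }
  mask
}

# 8-connected component labelling of a logical mask via the pixel adjacency
# graph (igraph); returns an integer matrix of labels, 0 = background
.label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  ny <- nrow(mask); nx <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, ny, nx)
  if (length(idx) == 0L) return(labels)
  row <- ((idx - 1L) %% ny) + 1L
  col <- ((idx - 1L) %/% ny) + 1L
  inmask <- logical(ny * nx)
  inmask[idx] <- TRUE
  # neighbour offsets (down, right, and the two diagonals for 8-conn);
  # each undirected edge is generated once
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (off in offs) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= ny & c2 >= 1L & c2 <= nx
    nb <- (c2[ok] - 1L) * ny + r2[ok]
    keep <- inmask[nb]
    from <- c(from, idx[ok][keep])
    to <- c(to, nb[keep])
  }
  # map pixel indices to consecutive vertex ids
  vid <- integer(ny * nx)
  vid[idx] <- seq_along(idx)
  g <- igraph::graph_from_edgelist(cbind(vid[from], vid[to]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  labels[idx] <- as.integer(comp)
  labels
}

#' Extract particle observations from a binary mask
#'
#' Labels connected foreground components (8-connected by default), sizes
#' each as pixel count divided by the square of the pixel scale, and flags
#' components touching the image border.
#'
#' @param mask logical matrix from [threshold_image()] (rows = y).
#' @param calib [image_calibration()]; its pixel dimensions must match the
#'   mask.
#' @param connectivity 8 (default) or 4.
#' @return A data.frame with one row per particle: `particle_id`,
#'   `n_pixels`, `area_um2`, `d_pa_um` (equivalent projected-area circle
#'   diameter), `x_um`, `y_um` (centroid), `touches_edge`.
#' @export
extract_particles <- function(mask, calib = image_calibration(),
                              connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (nrow(mask) != calib$ny || ncol(mask) != calib$nx) {
    stop(sprintf("mask is %d x %d px but calibration implies %d x %d",
                 nrow(mask), ncol(mask), calib$ny, calib$nx), call. = FALSE)
  }
  labels <- .label_components(mask, connectivity)
  idx <- which(labels > 0L)
  if (length(idx) == 0L) {
    return(data.frame(particle_id = integer(0), n_pixels = integer(0),
                      area_um2 = numeric(0), d_pa_um = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      touches_edge = logical(0)))
  }
  lab <- labels[idx]
  ny <- nrow(mask); nx <- ncol(mask)
  row <- ((idx - 1L) %% ny) + 1L
  col <- ((idx - 1L) %/% ny) + 1L
  npix <- tabulate(lab)
  ids <- seq_along(npix)
  ppm <- calib$pixels_per_micron
  # pixel centres at (i - 0.5)/ppm
  cx <- (vapply(split(col, lab), mean, 0) - 0.5) / ppm
  cy <- (vapply(split(row, lab), mean, 0) - 0.5) / ppm
  edge <- vapply(split(row == 1L | row == ny | col == 1L | col == nx, lab),
                 any, NA)
  area <- npix / ppm^2
  data.frame(particle_id = ids,
             n_pixels = npix,
             area_um2 = area,
             d_pa_um = 2 * sqrt(area / pi),
             x_um = as.numeric(cx),
             y_um = as.numeric(cy),
             touches_edge = as.logical(edge))
}

#' Apply the particle exclusion rules
#'
#' Retains particles with `min_area <= area <= max_area` that do not touch
#' the image border (when `exclude_edge` is on).  Order-preserving and
#' idempotent.
#'
#' @param particles data.frame from [extract_particles()] (needs columns
#'   `area_um2` and `touches_edge`).
#' @param rules [filter_rules()].
#' @param keep_excluded logical; if `TRUE` all rows are returned with an
#'   `exclusion_reason` column (`NA` for retained rows) for audit output.
#' @return Filtered data.frame (a subset of the input rows).
#' @export
filter_particles <- function(particles, rules = filter_rules(),
                             keep_excluded = FALSE) {
  stopifnot(is.data.frame(particles),
            all(c("area_um2", "touches_edge") %in% names(particles)))
  reason <- rep(NA_character_, nrow(particles))
  reason[particles$area_um2 > rules$max_area] <- "above_max_area"
  reason[particles$area_um2 < rules$min_area] <- "below_min_area"
  if (rules$exclude_edge) {
    reason[is.na(reason) & particles$touches_edge] <- "touches_edge"
  }
  if (keep_excluded) {
    particles$exclusion_reason <- reason
    particles
  } else {
    particles[is.na(reason), , drop = FALSE]
  }
}

#' Analytic edge-exclusion probability
#'
#' Probability that a circle of diameter `d` placed uniformly at random on
#' a `W x H` field touches the field border and is therefore excluded:
#' `1 - (W - d)(H - d) / (W H)`.  For 10-um particles on the default
#' 450 x 600 um field this is 3.9%, consistent with the rough "about 5%"
#' magnitude usually quoted; it decreases quickly for smaller particles.
#'
#' @param d particle diameter, um (vectorised); must be below both field
#'   dimensions.
#' @param calib [image_calibration()].
#' @return Exclusion probability in `[0, 1)`.
#' @export
edge_exclusion_fraction <- function(d, calib = image_calibration()) {
  W <- calib$image_width; H <- calib$image_height
  if (any(d < 0) || any(d >= min(W, H))) {
    stop("`d` must satisfy 0 <= d < min(image width, height)", call. = FALSE)
  }
  1 - (W - d) * (H - d) / (W * H)
}

#' @export
print.pas_calibration <- function(x, ...) {
  cat(sprintf(
    "<image calibration> %.3g px/um, field %g x %g um (%d x %d px)\n",
    x$pixels_per_micron, x$image_width, x$image_height, x$nx, x$ny))
  invisible(x)
}
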