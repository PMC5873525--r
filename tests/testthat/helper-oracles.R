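# Independent oracles: literal closed-form evaluations and brute-force
# searches, deliberately written without reusing package internals.

# slip correction straight from the printed single-expression form
oracle_cc <- function(d_m, lambda_m = 66.5e-9) {
  1 + (lambda_m / d_m) * (2.514 + 0.800 * exp(-0.55 * d_m / lambda_m))
}

# Sutherland viscosity and Stokes+slip settling, literal constants
oracle_mu <- function(T = 293.15) 1.458e-6 * T^1.5 / (T + 110.4)

oracle_vt <- function(da_m, T = 293.15) {
  1000 * da_m^2 * 9.80665 * oracle_cc(da_m) / (18 * oracle_mu(T))
}

oracle_diffusion <- function(d_m, T = 293.15) {
  1.380649e-23 * T * oracle_cc(d_m) / (3 * pi * oracle_mu(T) * d_m)
}

# exhaustive triangle-criterion search over every candidate threshold:
# distance from (t, h[t]) to the chord from the histogram peak to the far
# end of the longer tail (unnormalised numerator is enough for the argmax)
oracle_triangle <- function(h) {
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  if ((hi - peak) >= (peak - lo)) { a <- peak; b <- hi } else { a <- lo; b <- peak }
  x1 <- peak; y1 <- h[peak]
  x2 <- if (a == peak) b else a; y2 <- h[x2]
  best <- -Inf; best_t <- a
  for (t in a:b) {
    dist <- abs((y2 - y1) * t - (x2 - x1) * h[t] + x2 * y1 - y2 * x1)
    if (dist > best) { best <- dist; best_t <- t }
  }
  best_t - 1L
}

# brute-force two-class Shannon entropy criterion over all 256 thresholds
oracle_max_entropy <- function(h) {
  p <- h / sum(h)
  P <- cumsum(p)
  best <- -Inf; best_t <- NA_integer_
  for (t in seq_len(length(h) - 1L)) {
    w0 <- P[t]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    p0 <- p[1:t][p[1:t] > 0] / w0
    p1 <- p[(t + 1L):length(h)][p[(t + 1L):length(h)] > 0] / w1
    H <- -sum(p0 * log(p0)) - sum(p1 * log(p1))
    if (H > best) { best <- H; best_t <- t }
  }
  best_t - 1L
}

# a laid-out set of well-separated discs on a jittered grid, guaranteeing
# no two discs touch (for segmentation round-trip tests)
make_disc_layout <- function(calib, d_range = c(3, 14), spacing = 36,
                             margin = 20, seed = 99) {
  xs <- seq(margin, calib$image_width - margin, by = spacing)
  ys <- seq(margin, calib$image_height - margin, by = spacing)
  grid <- expand.grid(x_um = xs, y_um = ys)
  withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed(seed, {
    grid$x_um <- grid$x_um + runif(nrow(grid), -6, 6)
    grid$y_um <- grid$y_um + runif(nrow(grid), -6, 6)
    grid$d_pa_um <- runif(nrow(grid), d_range[1], d_range[2])
    grid
  })
}

# random plausible particle tables for model-ordering properties
random_particle_table <- function(n = 200) {
  data.frame(d_pa_um = exp(rnorm(n, log(2), log(2.5))))
}
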