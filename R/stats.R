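# Comparison statistics for multi-occasion sampler studies: mixed-model
# intraclass correlation with basic bootstrap CIs, paired squared-deviation
# tests between analysis models, through-origin regression, descriptives.

# run expr under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.check_study_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("location", "time", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("study table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"occasion" %in% names(table)) {
    table$occasion <- interaction(table$location, table$time, drop = TRUE)
  }
  table$location <- factor(table$location)
  table$time <- factor(table$time)
  table$occasion <- factor(table$occasion)
  if (nlevels(table$occasion) < 2L) {
    stop("need at least 2 measurement occasions", call. = FALSE)
  }
  if (max(table(table$occasion)) < 2L) {
    stop("need at least 2 replicates in at least one occasion",
         call. = FALSE)
  }
  table
}

#' Intraclass correlation from a linear mixed model
#'
#' Fits, by REML, `value ~ location + time + (1 | occasion)` — fixed
#' location and time effects with a random intercept for each measurement
#' occasion — and returns `ICC = var_between / (var_between + var_within)`,
#' the share of residual (after fixed effects) variance attributable to
#' occasions.  A high ICC means the device separates occasions well
#' relative to its replicate noise.
#'
#' @param table data.frame with columns `location`, `time`, `value` and
#'   optionally `occasion` (defaults to the location x time interaction).
#' @return Object of class `pas_icc`: `icc`, `var_between`, `var_within`,
#'   `singular` (TRUE when the between-occasion variance is estimated at
#'   zero, in which case `icc = 0`), `n`, and the `lme4` fit.
#' @export
icc_mixed <- function(table) {
  table <- .check_study_table(table)
  fit <- suppressMessages(lme4::lmer(
    value ~ location + time + (1 | occasion), data = table, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_b <- vc$vcov[vc$grp == "occasion"]
  var_w <- vc$vcov[vc$grp == "Residual"]
  singular <- var_b <= 0 || lme4::isSingular(fit)
  icc <- if (var_b + var_w > 0) var_b / (var_b + var_w) else 0
  structure(list(icc = icc, var_between = var_b, var_within = var_w,
                 singular = singular, n = nrow(table), fit = fit),
            class = "pas_icc")
}

#' Basic bootstrap confidence interval for the ICC
#'
#' Forms the basic bootstrap interval
#' `(2*icc_hat - q_0.975, 2*icc_hat - q_0.025)` clipped to `[0, 1]` from a
#' bootstrap distribution of refitted ICCs.  The default resampling is
#' parametric — response vectors simulated from the REML fit and refitted
#' — which propagates the dominant uncertainty, the between-occasion
#' variance estimated from few clusters.  Nonparametric alternatives:
#' `unit = "occasion"` resamples whole occasions (relabelled so duplicate
#' draws stay distinct clusters) and `unit = "replicate"` resamples
#' replicates within occasions; the latter holds the between-occasion
#' variability essentially fixed and yields far-too-narrow intervals, so
#' it is offered only for sensitivity analysis.  Even the parametric
#' interval is moderately anti-conservative with only 12 occasions (see
#' the methods vignette).
#'
#' @inheritParams icc_mixed
#' @param B number of bootstrap resamples.
#' @param seed integer seed; a fixed seed gives a reproducible interval.
#' @param level confidence level.
#' @param unit `"parametric"` (default), `"occasion"` or `"replicate"`.
#' @return List with `ci_low`, `ci_high`, `icc`, `n_bootstrap`,
#'   `n_failed` (refits that errored; skipped and counted), `level`.
#' @export
icc_bootstrap_ci <- function(table, B = 1000L, seed = NULL, level = 0.95,
                             unit = c("parametric", "occasion",
                                      "replicate")) {
  unit <- match.arg(unit)
  table <- .check_study_table(table)
  fit0 <- icc_mixed(table)
  est <- fit0$icc
  occ_rows <- split(seq_len(nrow(table)), table$occasion)
  boot <- .with_seed(seed, {
    sims <- if (unit == "parametric") {
      stats::simulate(fit0$fit, nsim = B)
    }
    vapply(seq_len(B), function(b) {
      d <- switch(unit,
        parametric = {
          d <- table
          d$value <- sims[[b]]
          d
        },
        replicate = {
          rows <- unlist(lapply(occ_rows, function(r) {
            r[sample.int(length(r), length(r), replace = TRUE)]
          }), use.names = FALSE)
          table[rows, , drop = FALSE]
        },
        occasion = {
          picked <- sample(seq_along(occ_rows), length(occ_rows),
                           replace = TRUE)
          d <- table[unlist(occ_rows[picked], use.names = FALSE), ,
                     drop = FALSE]
          # relabel so a twice-drawn occasion stays two distinct clusters
          d$occasion <- factor(rep(seq_along(picked),
                                   lengths(occ_rows)[picked]))
          d
        })
      tryCatch(icc_mixed(d)$icc, error = function(e) NA_real_)
    }, numeric(1))
  })
  failed <- sum(is.na(boot))
  if (failed > 0L) {
    warning(failed, " of ", B, " bootstrap refits failed and were skipped",
            call. = FALSE)
  }
  q <- stats::quantile(boot, c((1 - level) / 2, (1 + level) / 2),
                       na.rm = TRUE, names = FALSE)
  list(ci_low = max(0, 2 * est - q[2]), ci_high = min(1, 2 * est - q[1]),
       icc = est, n_bootstrap = B, n_failed = failed, level = level)
}

#' Paired squared-deviation comparison of analysis models
#'
#' For each sampler measurement, the squared distance to the reference
#' mean of its occasion, `d_i = (x_i - ref(occasion_i))^2`, summarises how
#' far an analysis model is from the reference instrument.  Because all
#' models are deterministic transforms of the same raw samplers, models
#' are compared with paired t-tests on the per-sampler `d_i`.
#'
#' @param values long data.frame with columns `model`, `sampler_id`,
#'   `occasion`, `value` — the same samplers must appear under every
#'   model.
#' @param reference_means named numeric vector of reference ("true")
#'   occasion means, names matching `occasion` levels.
#' @return List with `summary` (per model: n, mean and SD of squared
#'   deviations) and `pairwise` (model pairs with mean difference and
#'   paired t-test p-value).
#' @export
model_deviation_test <- function(values, reference_means) {
  stopifnot(is.data.frame(values),
            all(c("model", "sampler_id", "occasion", "value") %in%
                  names(values)))
  occ <- as.character(values$occasion)
  if (!all(occ %in% names(reference_means))) {
    stop("missing reference mean for occasion(s): ",
         paste(unique(occ[!occ %in% names(reference_means)]),
               collapse = ", "), call. = FALSE)
  }
  values$devsq <- (values$value - reference_means[occ])^2
  models <- unique(values$model)
  key <- function(m) {
    d <- values[values$model == m, ]
    d <- d[order(d$occasion, d$sampler_id), ]
    d
  }
  per <- lapply(models, key)
  names(per) <- models
  ids <- lapply(per, function(d) paste(d$occasion, d$sampler_id))
  for (i in seq_along(per)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      stop("models are not paired: sampler/occasion sets differ between `",
           models[1], "` and `", models[i], "`", call. = FALSE)
    }
  }
  summary <- data.frame(
    model = models,
    n = vapply(per, nrow, 0L),
    mean_sq_dev = vapply(per, function(d) mean(d$devsq), 0),
    sd_sq_dev = vapply(per, function(d) stats::sd(d$devsq), 0),
    row.names = NULL)
  pairs <- utils::combn(models, 2L, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(p) {
    a <- per[[p[1]]]$devsq; b <- per[[p[2]]]$devsq
    if (length(a) < 2L) {
      stop("paired t-test needs at least 2 pairs", call. = FALSE)
    }
    diffs <- a - b
    p_val <- if (stats::sd(diffs) == 0) {
      if (all(diffs == 0)) 1 else 0  # degenerate: identical or constant shift
    } else {
      stats::t.test(a, b, paired = TRUE)$p.value
    }
    data.frame(model_a = p[1], model_b = p[2],
               mean_diff = mean(diffs), p_value = p_val)
  }))
  list(summary = summary, pairwise = pairwise)
}

#' Linear regression with intercept forced through zero
#'
#' `slope = sum(x*y) / sum(x^2)`; the coefficient of determination is the
#' through-origin (uncentred) `R^2 = 1 - RSS / sum(y^2)`.
#'
#' @param x,y numeric vectors of equal length (>= 2 points).
#' @return List with `slope` and `r_squared`.
#' @examples
#' origin_regression(c(1, 2), c(2, 4))  # slope 2, R^2 1
#' @export
origin_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  sxx <- sum(x^2)
  if (sxx == 0) stop("all x are zero: slope undefined", call. = FALSE)
  slope <- sum(x * y) / sxx
  syy <- sum(y^2)
  r2 <- if (syy == 0) NA_real_ else 1 - sum((y - slope * x)^2) / syy
  list(slope = slope, r_squared = r2)
}

#' Descriptive statistics
#'
#' Mean, SD, coefficient of variation, median, quartiles (linear
#' interpolation, R type 7), min and max.
#'
#' @param values numeric vector (>= 1 value, NA removed).
#' @return One-row data.frame with columns `n`, `mean`, `sd`, `cv`,
#'   `median`, `q1`, `q3`, `min`, `max`.  `cv = sd/mean` is `NA` (with a
#'   warning) when the mean is zero.
#' @export
descriptives <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  m <- mean(values)
  s <- if (length(values) > 1L) stats::sd(values) else 0
  cv <- if (m == 0) {
    warning("mean is zero: CV undefined", call. = FALSE)
    NA_real_
  } else {
    s / m
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(values), mean = m, sd = s, cv = cv,
             median = q[2], q1 = q[1], q3 = q[3],
             min = min(values), max = max(values))
}

#' @export
print.pas_icc <- function(x, ...) {
  cat(sprintf(paste0("<ICC> %.3f  (between %.4g, within %.4g, n = %d%s)\n"),
              x$icc, x$var_between, x$var_within, x$n,
              if (x$singular) ", singular fit" else ""))
  invisible(x)
}
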