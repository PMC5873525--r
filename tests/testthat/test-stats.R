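test_that("icc_mixed: definitional cases and variance recovery", {
  # identical replicates within occasions, differing across -> ICC = 1
  tab <- expand.grid(location = paste0("L", 1:4), time = paste0("T", 1:3),
                     replicate = 1:3)
  # a random occasion effect (orthogonal to nothing in particular) makes
  # replicates identical within occasions while occasions differ
  set.seed(8)
  occ <- interaction(tab$location, tab$time)
  eff <- rnorm(nlevels(occ))
  tab$value <- eff[as.integer(occ)]
  expect_equal(icc_mixed(tab)$icc, 1, tolerance = 1e-6)
  # pure replicate noise -> ICC ~ 0 (singular fit flagged)
  tab$value <- rnorm(nrow(tab))
  r0 <- icc_mixed(tab)
  expect_lt(r0$icc, 0.3)
  # balanced design with var_b = var_w: ICC ~ 0.5 on average (the
  # between-variance carries only ~11 df, so single studies scatter)
  rs <- lapply(1:10, function(s) icc_mixed(simulate_study(
    study_spec(replicates = 100, var_between = 0.04, var_within = 0.04),
    seed = 14 + s)))
  expect_equal(mean(vapply(rs, `[[`, 0, "icc")), 0.5, tolerance = 0.1)
  for (r in rs) {
    expect_equal(r$icc, r$var_between / (r$var_between + r$var_within))
  }
  # degenerate designs are rejected
  one_occ <- data.frame(location = "L1", time = "T1", value = rnorm(5))
  expect_error(icc_mixed(one_occ), "occasions")
  singles <- expand.grid(location = paste0("L", 1:4),
                         time = paste0("T", 1:3))
  singles$value <- rnorm(nrow(singles))
  expect_error(icc_mixed(singles), "replicates")
})

test_that("icc_bootstrap_ci: deterministic under seed, interval sane,
           width shrinks with replication", {
  tab <- simulate_study(study_spec(), seed = 5)
  ci1 <- icc_bootstrap_ci(tab, B = 100, seed = 42)
  ci2 <- icc_bootstrap_ci(tab, B = 100, seed = 42)
  expect_identical(ci1[c("ci_low", "ci_high")], ci2[c("ci_low", "ci_high")])
  expect_true(ci1$ci_low >= 0 && ci1$ci_high <= 1 &&
                ci1$ci_low <= ci1$ci_high)
  expect_error(icc_bootstrap_ci(
    data.frame(location = "L1", time = "T1", value = rnorm(6))))
  # replicate-unit widths shrink with replication, in expectation
  # (scaled down from the design-size experiment: 8 studies, B = 39);
  # the replicate unit is used because its width tracks within-occasion
  # precision directly
  width <- function(n_rep, seed) {
    d <- simulate_study(study_spec(replicates = n_rep), seed = seed)
    ci <- icc_bootstrap_ci(d, B = 39, seed = seed, unit = "replicate")
    ci$ci_high - ci$ci_low
  }
  w10 <- mean(vapply(1:8, function(s) width(10L, s), 0))
  w40 <- mean(vapply(1:8, function(s) width(40L, s), 0))
  expect_lt(w40, w10)
})

test_that("parametric basic bootstrap CI covers the true ICC far better
           than replicate resampling", {
  # Scaled down from a 500-study experiment to 24 studies at B = 199.
  # With 12 occasions the basic interval is moderately anti-conservative
  # (~0.8 observed coverage; methods vignette) -- the bound below is the
  # 0.005 binomial tail at coverage 0.79, and the replicate-unit
  # comparison checks the ordering that motivated the default.
  cover <- function(unit, B) {
    vapply(1:24, function(s) {
      d <- simulate_study(study_spec(var_between = 0.045,
                                     var_within = 0.045), seed = 100 + s)
      ci <- icc_bootstrap_ci(d, B = B, seed = s, unit = unit)
      ci$ci_low <= 0.5 && ci$ci_high >= 0.5
    }, NA)
  }
  hits <- cover("parametric", 199)
  expect_gte(sum(hits), 14)
})

test_that("model deviation test: pairing, degenerate and power cases", {
  occasions <- paste0("O", 1:4)
  ref <- setNames(c(1, 2, 3, 4), occasions)
  base <- expand.grid(sampler_id = 1:25, occasion = occasions,
                      stringsAsFactors = FALSE)
  set.seed(9)
  base$value <- ref[base$occasion] + rnorm(nrow(base), 0, 0.5)
  # identical model outputs: zero mean difference, p = 1
  two <- rbind(cbind(base, model = "A"), cbind(base, model = "B"))
  out <- model_deviation_test(two, ref)
  expect_equal(out$pairwise$mean_diff, 0)
  expect_equal(out$pairwise$p_value, 1)
  expect_equal(out$summary$mean_sq_dev[1], mean((base$value -
                                                   ref[base$occasion])^2))
  # model B uniformly closer to the reference: detected at n = 100
  worse <- base
  worse$value <- ref[worse$occasion] +
    (base$value - ref[base$occasion]) * 2
  two2 <- rbind(cbind(worse, model = "A"), cbind(base, model = "B"))
  out2 <- model_deviation_test(two2, ref)
  msd <- setNames(out2$summary$mean_sq_dev, out2$summary$model)
  expect_lt(msd[["B"]], msd[["A"]])
  expect_lt(out2$pairwise$p_value, 0.05)
  # mismatched pairing is an error
  bad <- rbind(cbind(base, model = "A"),
               cbind(base[-1, ], model = "B"))
  expect_error(model_deviation_test(bad, ref), "paired")
  # a single pair cannot be tested
  single <- rbind(
    data.frame(sampler_id = 1, occasion = "O1", value = 1.2, model = "A"),
    data.frame(sampler_id = 1, occasion = "O1", value = 1.1, model = "B"))
  expect_error(model_deviation_test(single, ref), "2 pairs")
  # unknown occasion in the data
  expect_error(model_deviation_test(
    rbind(cbind(base, model = "A"),
          cbind(transform(base, occasion = "O9"), model = "B")), ref),
    "reference mean")
})

test_that("origin regression equals the closed form", {
  expect_equal(origin_regression(c(1, 2), c(2, 4)),
               list(slope = 2, r_squared = 1))
  set.seed(12)
  x <- rnorm(60); y <- 1.7 * x + rnorm(60, 0, 0.4)
  fit <- origin_regression(x, y)
  expect_equal(fit$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  # agrees with lm(y ~ 0 + x)
  lmfit <- lm(y ~ 0 + x)
  expect_equal(fit$slope, unname(coef(lmfit)), tolerance = 1e-12)
  expect_equal(fit$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)
  expect_equal(origin_regression(x, rep(0, 60))$slope, 0)
  expect_error(origin_regression(rep(0, 5), rnorm(5)), "zero")
  expect_error(origin_regression(1, 2), "2 points")
})

test_that("descriptives: definitional values and quartile ordering", {
  d <- descriptives(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$median, 2)
  expect_equal(d$cv, d$sd / d$mean)
  const <- descriptives(rep(4.2, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  set.seed(3)
  for (k in 1:10) {
    r <- descriptives(rnorm(sample(3:50, 1)))
    expect_true(r$q1 <= r$median && r$median <= r$q3)
    expect_true(r$min <= r$q1 && r$q3 <= r$max)
  }
  # quartiles use linear interpolation (type 7)
  v <- c(1, 2, 3, 10)
  expect_equal(descriptives(v)$q1, quantile(v, 0.25, type = 7,
                                            names = FALSE))
  expect_warning(z <- descriptives(c(-1, 1)), "CV")
  expect_true(is.na(z$cv))
})
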