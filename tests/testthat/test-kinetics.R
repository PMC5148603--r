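mkCourse <- function(time, fraction, sd = 0.01, n = 3,
                     condition = list(substrateConc = 10)) {
  new("TimeCourse", condition = condition,
      points = data.frame(time = time, fraction = fraction, sd = sd,
                          n = n, flags = ""))
}

test_that("time courses aggregate replicates to mean and SD", {
  fits <- data.frame(time_min = rep(c(5, 30), each = 3),
                     fraction_unfolded = c(0.06, 0.07, 0.08,
                                           0.28, 0.29, 0.30))
  tc <- assembleTimeCourse(fits, condition = list(substrateConc = 10))
  p <- coursePoints(tc)
  expect_equal(p$fraction, c(0.07, 0.29))
  expect_equal(p$sd[2], 0.01)
  expect_equal(p$n, c(3L, 3L))
})

test_that("single replicates report missing SD, never zero", {
  fits <- data.frame(time_min = c(5, 30),
                     fraction_unfolded = c(0.07, 0.29))
  p <- coursePoints(assembleTimeCourse(fits, condition = list()))
  expect_true(all(is.na(p$sd)))
  expect_equal(p$n, c(1L, 1L))
})

test_that("mixed conditions are rejected, noisy non-monotone courses kept", {
  fits <- data.frame(time_min = c(5, 30),
                     fraction_unfolded = c(0.07, 0.29),
                     inhibitor_conc = c(1, 2))
  expect_error(assembleTimeCourse(fits), "mixed conditions")
  wiggly <- data.frame(time_min = c(1, 2, 3),
                       fraction_unfolded = c(0.2, 0.15, 0.25))
  expect_equal(coursePoints(assembleTimeCourse(wiggly,
                                               condition = list()))$fraction,
               c(0.2, 0.15, 0.25))
})

test_that("spontaneous subtraction is pointwise with quadrature SDs", {
  cat5 <- mkCourse(c(5, 10), c(0.603, 0.80), sd = 0.023)
  sp5 <- mkCourse(c(5, 10), c(0.070, 0.12), sd = 0.007)
  out <- coursePoints(subtractSpontaneous(cat5, sp5))
  expect_equal(out$fraction[1], 0.533)
  expect_equal(out$sd[1], sqrt(0.023^2 + 0.007^2))
  ## identity: x - x = 0 everywhere
  self <- coursePoints(subtractSpontaneous(cat5, cat5))
  expect_true(all(self$fraction == 0))
  ## negative differences clip to zero with a flag
  neg <- coursePoints(subtractSpontaneous(sp5, cat5))
  expect_true(all(neg$fraction == 0))
  expect_true(all(grepl("clipped_at_zero", neg$flags)))
  ## mismatched grids rejected unless interpolation is requested
  off <- mkCourse(c(4, 9), c(0.05, 0.10))
  expect_error(subtractSpontaneous(cat5, off), "interpolate")
  interp <- subtractSpontaneous(cat5, off, interpolate = TRUE)
  expect_equal(coursePoints(interp)$time, c(5, 10))
})

test_that("initial rates are exact on proportional data", {
  tc <- mkCourse(1:3, c(0.1, 0.2, 0.3))
  r <- initialRate(tc)
  expect_equal(r@rate, 0.1)
  expect_equal(r@molarRate, 1.0)  # substrate 10 uM
  expect_equal(r@molarRate, r@rate * r@substrateConc)
})

test_that("depleted points are excluded and the estimate is unchanged by them", {
  base <- mkCourse(1:3, c(0.1, 0.2, 0.3))
  withLate <- mkCourse(c(1:3, 10), c(0.1, 0.2, 0.3, 0.9))
  r1 <- initialRate(base)
  r2 <- initialRate(withLate)
  expect_equal(r1@rate, r2@rate)
  expect_equal(r2@excluded$reason, "substrate_depletion")
  expect_equal(r2@excluded$time, 10)
  ## the linear-phase cap also excludes, with its own reason
  r3 <- initialRate(mkCourse(c(1, 2, 12), c(0.05, 0.1, 0.25)),
                    maxTime = 10)
  expect_equal(r3@excluded$reason, "beyond_linear_phase")
})

test_that("rates are withheld, not fabricated, below two usable points", {
  tc <- mkCourse(c(1, 2), c(0.5, 0.9))
  r <- initialRate(tc)
  expect_true(is.na(r@rate))
  expect_true(is.na(r@molarRate))
  expect_equal(unique(r@excluded$reason), "substrate_depletion")
  expect_equal(r@condition$withheld, "fewer_than_2_usable_points")
})

test_that("noiseless model data at small times recover the total rate", {
  p <- kineticPreset("wt", kSpont = 0.0114, efficacy = 1.6,
                     inhibitorConc = 1, substrateConc = 10)
  t <- seq(0.01, 0.05, by = 0.01)
  tc <- mkCourse(t, twoStateFraction(t, p))
  r <- initialRate(tc)
  expect_lt(abs(r@rate - (0.0114 + 0.16)) / (0.0114 + 0.16), 0.02)
})

test_that("efficacy regression reproduces an exact dose line", {
  mk <- function(rate, conc) {
    tc <- mkCourse(1:2, rate * 1:2,
                   condition = list(substrateConc = 10,
                                    inhibitorConc = conc))
    initialRate(tc)
  }
  eff <- efficacyRegression(list(mk(0.016, 1), mk(0.008, 0.5),
                                 mk(0.004, 0.25)))
  expect_equal(eff@efficacy, 0.16, tolerance = 1e-9)
  expect_equal(eff@intercept, 0, tolerance = 1e-12)
  expect_equal(eff@throughOrigin, 0.16, tolerance = 1e-9)
  expect_equal(eff@rsquared, 1, tolerance = 1e-9)
  ## scaled to the printed example: fraction rates 0.16/0.08/0.04 at
  ## 1/0.5/0.25 uM and 10 uM substrate give 1.6 molecules per molecule
  ## per minute
  eff2 <- efficacyRegression(list(mk(0.16, 1), mk(0.08, 0.5),
                                  mk(0.04, 0.25)))
  expect_equal(eff2@efficacy, 1.6, tolerance = 1e-9)
  zero <- efficacyRegression(list(mk(0, 1), mk(0, 0.5)))
  expect_equal(zero@efficacy, 0)
  expect_error(efficacyRegression(list(mk(0.1, 1))), "distinct")
})

test_that("the global kinetic model recovers generating parameters", {
  ## replicate fraction courses from the two-state model at default
  ## measurement noise on the fraction scale
  set.seed(17)
  mkNoisy <- function(conc, eff = 1.6, kDecay = 0) {
    p <- kineticPreset("x", kSpont = 0.0114, efficacy = eff,
                      inhibitorConc = conc, kDecay = kDecay)
    t <- c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10)
    reps <- vapply(1:3, function(i)
      twoStateFraction(t, p) + stats::rnorm(length(t), 0, 0.005),
      numeric(length(t)))
    mkCourse(t, rowMeans(reps), sd = apply(reps, 1, stats::sd),
             condition = list(substrateConc = 10,
                              inhibitorConc = conc))
  }
  courses <- list(mkNoisy(0), mkNoisy(1), mkNoisy(0.5), mkNoisy(0.25))
  fit <- fitKineticModel(courses, fixKDecay = TRUE)
  expect_lt(abs(fit$efficacy - 1.6) / 1.6, 0.10)
  expect_lt(abs(fit$kSpont - 0.0114) / 0.0114, 0.10)
  expect_match(fit$note, "fixed at 0")
  ## and through the full measured chain the efficacy still recovers
  reg <- presetRegistry()
  pipe <- efficacyPipeline(reg$kinetic$wt, concs = c(1.0, 0.5, 0.25),
                           seed = 17)
  chainFit <- fitKineticModel(c(list(pipe$spontaneous), pipe$courses),
                              fixKDecay = TRUE)
  expect_lt(abs(chainFit$efficacy - 1.6) / 1.6, 0.10)
})

test_that("inhibitor-activity decay is detected by model comparison", {
  reg <- presetRegistry()
  pipe <- efficacyPipeline(reg$kinetic$e15k, concs = c(2.0, 1.0, 0.5),
                           seed = 18)
  courses <- c(list(pipe$spontaneous), pipe$courses)
  noDecay <- fitKineticModel(courses, fixKDecay = TRUE)
  withDecay <- fitKineticModel(courses, fixKDecay = FALSE)
  expect_lt(withDecay$aic, noDecay$aic)
  expect_gt(withDecay$kDecay, 0)
  expect_error(fitKineticModel(list(pipe$courses[[1]])), "control")
})
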