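test_that("dry-to-wet-weight conversions reproduce the reference levels", {
  expect_equal(convertDwToWw(10, "bone"), 4.97)     # reported bone ULN 5
  expect_equal(convertDwToWw(14, "bone"), 6.958)    # critical bone level 7
  expect_equal(convertDwToWw(162, "liver"), 40.5)
  expect_equal(convertDwToWw(32, "liver"), 8)
  expect_equal(convertDwToWw(4.5, "brain"), 1.035)  # brain ULN 1
  expect_equal(convertDwToWw(0, "bone"), 0)
  expect_equal(convertDwToWw(0, "brain"), 0)
  expect_error(convertDwToWw(1, "plasma"))
  expect_error(convertDwToWw(-1, "bone"), "non-negative")
})

test_that("population quantile bands are pointwise and order-preserving", {
  ages <- c(0, 1, 2)
  # a single individual: every quantile equals its trajectory
  one <- concExperiment(matrix(c(1, 2, 3), ncol = 1), ages)
  q <- populationQuantiles(one, "plasma")
  expect_equal(q$p5, c(1, 2, 3))
  expect_equal(q$median, c(1, 2, 3))
  expect_equal(q$p95, c(1, 2, 3))

  # constant series 1, 2, 3 across individuals
  three <- concExperiment(matrix(rep(c(1, 2, 3), each = 3), nrow = 3), ages)
  q3 <- populationQuantiles(three, "plasma")
  expect_equal(q3$median, rep(2, 3))

  # large sample against analytic lognormal quantiles
  set.seed(1)
  n <- 5000
  sdlog <- sqrt(log(1.25))
  draws <- matrix(exp(rnorm(n, sd = sdlog)), nrow = 1)
  ql <- populationQuantiles(concExperiment(draws, 0), "plasma")
  expect_equal(ql$median, 1, tolerance = 0.05)
  expect_equal(ql$p95, exp(qnorm(0.95) * sdlog), tolerance = 0.05)
  expect_equal(ql$p5, exp(qnorm(0.05) * sdlog), tolerance = 0.05)
  expect_true(ql$p5 <= ql$median && ql$median <= ql$p95)
})

test_that("max-median-difference summaries honour the tie-break and window rules", {
  ages <- seq(0, 2, by = 0.1)
  flat <- function(m, p95 = m) data.frame(age_years = ages, median = m,
                                          p5 = m, p95 = p95)
  # identical bands: difference 0, ratio 1, earliest timepoint
  r <- maxMedianDifference(flat(1), flat(1), c(0, 2))
  expect_equal(r$mDiff, 0)
  expect_equal(r$mRatio, 1)
  expect_equal(r$timepoint, 0)

  # constant offset: difference 1, ratio 2, earliest timepoint of the window
  r2 <- maxMedianDifference(flat(2), flat(1), c(0.5, 2))
  expect_equal(r2$mDiff, 1)
  expect_equal(r2$mRatio, 2)
  expect_equal(r2$timepoint, 0.5)

  # a bump peaking inside the window is located exactly
  bump <- flat(1)
  bump$median <- 1 + exp(-((ages - 1.3) / 0.2)^2)
  r3 <- maxMedianDifference(bump, flat(1), c(0, 2))
  expect_equal(r3$timepoint, 1.3)
  expect_equal(r3$mDiff, 1)
  # reported medians recompute the difference and ratio
  expect_equal(r3$mDiff, r3$mA - r3$mB)
  expect_equal(r3$mRatio, r3$mA / r3$mB)

  expect_error(maxMedianDifference(flat(1), flat(1), c(5, 6)), "window")
  shifted <- flat(1); shifted$age_years <- ages + 0.01
  expect_error(maxMedianDifference(flat(1), shifted, c(0, 2)), "grid")
})

test_that("body burden sums the compartments and tracks the mass balance", {
  params <- ModelParams()
  phys <- defaultPhysiology()
  zero <- simulateIndividual(typicalIndividual(params), foodOnlyScenario(),
                             params, phys, tEnd = 1,
                             initialAmounts = zeroAmounts)
  expect_equal(bodyBurden(zero, 1)$body_mg, 0, tolerance = 1e-12)

  traj <- simulateIndividual(typicalIndividual(params),
                             builtinScenario("GERMANY_2025"), params, phys,
                             tEnd = 2)
  bb <- bodyBurden(traj, 2)
  i <- nrow(traj)
  ident <- (traj$plasma[1] + traj$liver[1] + traj$brain[1] + traj$bone[1] +
              traj$rest[1] + traj$oralAbsorbed[i] + traj$depotReleased[i] -
              traj$urine[i]) / 1000
  expect_equal(bb$body_mg, ident, tolerance = 1e-3)
  # at 18 months the 11- and 12-month depots are still releasing
  mid <- traj$age_years[which.min(abs(traj$age_years - 1.5))]
  expect_gt(bodyBurden(traj, mid)$depotRemainder_mg, 0)
  # by 2 years every depot administered so far is exhausted (the last one,
  # given at 12 months, depletes within a year)
  expect_equal(bb$depotRemainder_mg, 0)
  expect_error(bodyBurden(traj, 1.9999), "grid")
})

test_that("reference-level flags use strict exceedance", {
  v <- data.frame(tissue = c("bone", "bone", "bone", "brain", "liver"),
                  conc_ww = c(0.668, 5, 31, 1.2, 3.9))
  f <- ulnFlags(v)
  expect_equal(f$exceeds_uln, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(f$exceeds_disease[3], TRUE)     # > 30 ug/g ww
  expect_true(is.na(f$exceeds_critical[4]))    # no critical level for brain
  expect_error(ulnFlags(data.frame(tissue = "plasma", conc_ww = 1)), "plasma")
  # inputs are not mutated
  expect_false("exceeds_uln" %in% names(v))
})

test_that("summary tables mirror the paired-contrast construction", {
  params <- ModelParams()
  pop <- samplePopulation(4, seed = 2, params = params)
  expA <- simulatePopulation(pop, builtinScenario("GERMANY_2025"),
                             params = params, tEnd = 2)
  expB <- simulatePopulation(pop, builtinScenario("FOOD_ONLY"),
                             params = params, tEnd = 2)
  s <- summaryTable(expA, expB, windows = list(c(0, 2)))
  expect_equal(nrow(s), 4L)
  expect_equal(s$mDiff, s$mA - s$mB)
  expect_equal(s$mRatio, s$mA / s$mB)
  expect_true(all(s$timepoint >= 0 & s$timepoint <= 2))
  # vaccines only add aluminium: the paired contrast is non-negative
  expect_true(all(s$mDiff >= -1e-12))
})
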