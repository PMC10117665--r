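test_that("MSD obeys the stationary and ballistic closed forms", {
  still <- data.frame(time_s = (0:20) * 0.05, x_m = 1e-3, y_m = -2e-3)
  m <- msdCurve(still, lags = c(0.05, 0.25, 0.5))
  expect_equal(m$msd, rep(0, 3))
  # ballistic r = v t: MSD(tau) = |v|^2 tau^2 exactly
  v <- c(2e-3, -1e-3)
  t <- (0:50) * 0.05
  ball <- data.frame(time_s = t, x_m = v[1] * t, y_m = v[2] * t)
  lags <- c(0.05, 0.1, 0.5, 1)
  m <- msdCurve(ball, lags = lags)
  expect_equal(m$msd, sum(v^2) * lags^2)
  # lag 0 gives 0; over-long lags are dropped with a warning
  expect_equal(msdCurve(ball, lags = 0)$msd, 0)
  expect_warning(m2 <- msdCurve(ball, lags = c(0.5, 10)), "dropped")
  expect_equal(nrow(m2), 1L)
})

test_that("random-walk MSD is linear at 4 D tau", {
  dt <- 0.05; sigma <- 1e-4
  D <- sigma^2 / (2 * dt)
  lags <- dt * (1:10)
  acc <- matrix(0, 40, 10)
  for (s in 1:40) {
    w <- generatePoolWalk(400, stepSigma = sigma, dt = dt, seed = 3000 + s)
    acc[s, ] <- msdCurve(w, lags = lags)$msd
  }
  expect_lt(max(abs(colMeans(acc) / (4 * D * lags) - 1)), 0.1)
})

test_that("MSD is invariant to time shifts of the track", {
  w <- generatePoolWalk(200, stepSigma = 1e-4, dt = 0.05, seed = 8)
  m1 <- msdCurve(w, lags = 0.05 * (1:10))
  w2 <- w; w2$time_s <- w2$time_s + 123.4
  m2 <- msdCurve(w2, lags = 0.05 * (1:10))
  expect_equal(m2$msd, m1$msd)
})

test_that("circular summary averages on the circle", {
  s <- circularSummary(rep(90, 10))
  expect_equal(s$meanDeg, 90)
  expect_equal(s$resultantLength, 1)
  # antipodal cancellation: undefined mean
  s <- circularSummary(c(0, 180))
  expect_true(s$undefined)
  expect_equal(s$resultantLength, 0)
  s <- circularSummary(c(85, 95))
  expect_equal(s$meanDeg, 90)
  expect_equal(s$resultantLength, cos(5 * pi / 180))
  # wrap-around: 350 and 10 average to 0, not 180
  expect_equal(circularSummary(c(350, 10))$meanDeg, 0)
})

test_that("source and sink deviations fold the circle onto [0, 90]", {
  expect_equal(sourceDeviation(90), 0)
  expect_equal(sourceDeviation(270), 0)
  expect_equal(sourceDeviation(30), 60)
  expect_equal(sinkDeviation(185), 5)
  grid <- seq(0, 359.5, by = 0.5)
  expect_true(all(sourceDeviation(grid) >= 0 & sourceDeviation(grid) <= 90))
  expect_equal(sourceDeviation(grid) + sinkDeviation(grid), rep(90, length(grid)))
})

test_that("chance-alignment probability matches the printed cohort value", {
  p <- chanceAlignmentPvalue(5, 30)
  expect_equal(p, (30 / 360)^5 * 12)
  expect_equal(p, 12^-4)
  expect_equal(signif(p, 2), 4.8e-5)
  expect_equal(chanceAlignmentPvalue(1, 30), 1)
  expect_error(chanceAlignmentPvalue(5, 25), "divide 360")
  # monotone decreasing in cohort size, increasing in window width
  ps <- vapply(1:6, chanceAlignmentPvalue, numeric(1), windowDeg = 30)
  expect_true(all(diff(ps) < 0))
  pw <- vapply(c(10, 20, 30, 45, 60), function(w)
    chanceAlignmentPvalue(4, w), numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("mobility classification follows the angle windows", {
  expect_equal(classifyMobility(92, 0.97), "intact")
  expect_equal(classifyMobility(270, 0.95), "intact")  # both upstream headings
  expect_equal(classifyMobility(185, 0.95), "disrupted")
  expect_equal(classifyMobility(5, 0.95), "disrupted")
  expect_equal(classifyMobility(120, 0.6), "recovering")
  expect_equal(classifyMobility(45, 0.3), "indeterminate")
  expect_equal(classifyMobility(NA, 0), "indeterminate")
  # thresholds are configurable
  expect_equal(classifyMobility(120, 0.6, list(recovering_dev = 20)),
               "indeterminate")
})

test_that("per-fish reports assemble summary, deviations and class", {
  tr <- simulateSwimmer(5, rotNoise = 0.05, strainRate = 1, dt = 0.01,
                        duration = 60, theta0Deg = 100, seed = 12)
  r <- mobilityReport(tr, meta = list(fish_id = 7, type = "typeI"))
  expect_s4_class(r, "MobilityReport")
  expect_equal(mobilityClass(r), "intact")
  expect_lt(r@sourceDeviationDeg, 10)
  expect_equal(r@sourceDeviationDeg + r@sinkDeviationDeg, 90)
  expect_equal(r@meta$fish_id, 7)
})

test_that("recovery trend interpolates the midpoint crossing", {
  # linear ramp 0 -> 90 over 20 min crosses 45 at 10 min
  t <- seq(0, 1200, length.out = 25)
  rt <- recoveryTrend(t, seq(0, 90, length.out = 25))
  expect_equal(rt$initialDeg, 0)
  expect_equal(rt$finalDeg, 90)
  expect_equal(rt$timeToHalf_s, 600)
  expect_true(rt$monotone)
  # constant series at the sink: no crossing, flagged by NA
  rt0 <- recoveryTrend(c(0, 300, 600), c(0, 0, 0))
  expect_true(is.na(rt0$timeToHalf_s))
  # non-monotone series: first crossing, monotone flag off
  rtn <- recoveryTrend(c(0, 100, 200, 300), c(10, 50, 30, 80))
  expect_false(rtn$monotone)
  expect_lt(rtn$timeToHalf_s, 100)
})

test_that("cohort table aggregates fish and reports alignment", {
  reports <- lapply(c(88, 92, 95, 85, 91), function(a)
    mobilityReport(rnorm(200, a, 3) %% 360))
  ct <- cohortTable(reports, windowDeg = 30)
  expect_equal(nrow(ct$table), 5L)
  expect_true(all(ct$table$class == "intact"))
  # all five means inside one 30-degree partition window
  expect_equal(ct$alignmentP, chanceAlignmentPvalue(5, 30))
  # spread cohort: no alignment claim
  spread <- lapply(c(10, 100, 200, 300, 45), function(a)
    mobilityReport(rnorm(200, a, 3) %% 360))
  expect_true(is.na(cohortTable(spread)$alignmentP))
})
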