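test_that("passive drift matches the torque balance of the quadrature", {
  expect_equal(passiveDrift(pi / 2, 1), 0, tolerance = 1e-15)
  expect_equal(passiveDrift(pi / 4, 1), -1)
  expect_equal(passiveDrift(3 * pi / 4, 1), 1)
  # independent oracle: solve torqueNumeric(..., thetaDot) = 0 for thetaDot
  b <- testBody()
  f <- flowField("pure_strain", strainRate = 1)
  for (th in c(pi / 4, 1.2, 2.2)) {
    root <- uniroot(function(td) torqueNumeric(b, 1e-3, f, c(0, 0), th, td),
                    c(-5, 5), tol = 1e-12)$root
    expect_equal(passiveDrift(th, 1), root, tolerance = 1e-8)
  }
})

test_that("active drift reduces to the passive law and vanishes at the goal", {
  th <- seq(0, 2 * pi, length.out = 33)
  expect_equal(activeDrift(th, 0, strainRate = 1.3),
               passiveDrift(th, 1.3))
  expect_equal(activeDrift(pi / 2, 7, goal = pi / 2, strainRate = 1), 0,
               tolerance = 1e-15)
  # marginal linearised rate at the goal when A = 2*eps
  h <- 1e-6
  slope <- (activeDrift(pi / 2 + h, 2, strainRate = 1) -
            activeDrift(pi / 2 - h, 2, strainRate = 1)) / (2 * h)
  expect_equal(slope, 0, tolerance = 1e-5)
  expect_error(activeDrift(0, -1), "nonnegative")
})

test_that("critical activity is twice the strain rate", {
  expect_equal(criticalActivity(1), 2)
  expect_equal(criticalActivity(0.5), 1)
  # just above threshold the source heading attracts from 80 degrees
  tr <- simulateSwimmer(activity = 2.4, rotNoise = 0, strainRate = 1,
                        dt = 0.005, duration = 120, theta0Deg = 80)
  final <- tail(headingDeg(tr), 1)
  drift <- function(th) activeDrift(th, 2.4, strainRate = 1)
  fixedPoint <- uniroot(drift, c(pi / 3, pi / 2))$root * 180 / pi
  expect_equal(final, fixedPoint, tolerance = 1e-2)
  # just below threshold it escapes
  tr <- simulateSwimmer(activity = 1.6, rotNoise = 0, strainRate = 1,
                        dt = 0.005, duration = 120, theta0Deg = 80)
  expect_gt(sourceDeviation(tail(headingDeg(tr), 1)), 20)
})

test_that("noiseless trajectories settle on the drift's fixed points", {
  # passive: sink axis from a generic start
  tr <- simulateSwimmer(0, rotNoise = 0, strainRate = 1, dt = 0.005,
                        duration = 20, theta0Deg = 60)
  expect_lt(min(tail(headingDeg(tr), 1), 360 - tail(headingDeg(tr), 1)), 0.5)
  # strong activity: stable point near the source heading
  tr <- simulateSwimmer(5, rotNoise = 0, strainRate = 1, dt = 0.005,
                        duration = 20, theta0Deg = 30)
  expect_lt(abs(tail(headingDeg(tr), 1) - 90), 0.5)
  # the unstable equilibrium is preserved exactly
  tr <- simulateSwimmer(0, rotNoise = 0, strainRate = 1, dt = 0.005,
                        duration = 5, theta0Deg = 90)
  expect_true(all(headingDeg(tr) == 90))
})

test_that("simulation is deterministic and stable-step guarded", {
  a <- simulateSwimmer(1, rotNoise = 0.05, strainRate = 1, dt = 0.01,
                       duration = 5, theta0Deg = 45, seed = 99)
  b <- simulateSwimmer(1, rotNoise = 0.05, strainRate = 1, dt = 0.01,
                       duration = 5, theta0Deg = 45, seed = 99)
  expect_identical(headingDeg(a), headingDeg(b))
  c <- simulateSwimmer(1, rotNoise = 0.05, strainRate = 1, dt = 0.01,
                       duration = 5, theta0Deg = 45, seed = 100)
  expect_false(identical(headingDeg(a), headingDeg(c)))
  expect_error(simulateSwimmer(30, rotNoise = 0, strainRate = 1, dt = 0.01,
                               duration = 5, theta0Deg = 45),
               "dt too large")
  # global RNG state is untouched
  set.seed(7); before <- .Random.seed
  simulateSwimmer(1, rotNoise = 0.05, strainRate = 1, dt = 0.01,
                  duration = 1, theta0Deg = 45, seed = 1)
  expect_identical(.Random.seed, before)
})

test_that("halving dt changes the noiseless endpoint at first order", {
  final <- function(dt) tail(headingDeg(
    simulateSwimmer(3, rotNoise = 0, strainRate = 1, dt = dt,
                    duration = 4, theta0Deg = 150)), 1)
  e1 <- abs(final(0.02) - final(0.0025))
  e2 <- abs(final(0.01) - final(0.0025))
  expect_lt(e2, e1)
  expect_lt(abs(final(0.01) - final(0.005)), 0.5)
})

test_that("activity is recovered from trajectories", {
  # noiseless: finite differences invert the Euler step exactly
  tr <- simulateSwimmer(1, rotNoise = 0, strainRate = 1, dt = 0.01,
                        duration = 20, theta0Deg = 40)
  est <- estimateActivity(tr, strainRate = 1)
  expect_equal(est$activity, 1, tolerance = 1e-3)
  # A = 0 with noise: estimate consistent with zero at this sample size
  ests <- sapply(1:5, function(s) {
    tr <- simulateSwimmer(0, rotNoise = 0.05, strainRate = 1, dt = 0.01,
                          duration = 20, theta0Deg = 40, seed = s)
    e <- estimateActivity(tr, strainRate = 1)
    c(e$activity, e$se)
  })
  expect_lt(mean(ests[1, ]), 2 * mean(ests[2, ]))
  # unbiased across seeds at three activity levels
  for (A in c(0, 1, 3)) {
    ests <- vapply(1:8, function(s) {
      tr <- simulateSwimmer(A, rotNoise = 0.05, strainRate = 1, dt = 0.01,
                            duration = 20, theta0Deg = 40, seed = 600 + s)
      estimateActivity(tr, strainRate = 1)$activity
    }, numeric(1))
    expect_lt(abs(mean(ests) - A), max(0.12, 0.06 * A))
  }
  # pinned at the goal: unidentifiable
  trPin <- simulateSwimmer(1, rotNoise = 0, strainRate = 1, dt = 0.01,
                           duration = 10, theta0Deg = 30)  # exact fixed point
  expect_error(estimateActivity(trPin, strainRate = 1), "unidentifiable")
})

test_that("trajectories round-trip through CSV plus JSON metadata", {
  tr <- simulateSwimmer(2, rotNoise = 0.05, strainRate = 1, dt = 0.01,
                        duration = 2, theta0Deg = 45, seed = 3)
  path <- file.path(withr::local_tempdir(), "traj.csv")
  writeTrajectory(tr, path)
  tr2 <- readTrajectory(path)
  expect_equal(sampleTimes(tr2), sampleTimes(tr))
  expect_equal(headingDeg(tr2), headingDeg(tr), tolerance = 1e-12)
  expect_equal(tr2@meta$strain_rate, 1)
})
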