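test_that("pure straining flow follows (eps*x, -eps*y) with a stagnation point", {
  f <- flowField("pure_strain", strainRate = 1)
  v <- velocityAt(f, 1, 1)
  expect_equal(v$u, 1)
  expect_equal(v$v, -1)
  expect_equal(unlist(velocityAt(f, 0, 0)), c(u = 0, v = 0))
  # stagnation at the centre for every pattern
  for (p in c("one_cell", "two_cell", "four_cell_bounded")) {
    fb <- flowField(p, 1, 1)
    v0 <- velocityAt(fb, 0, 0)
    if (p == "two_cell") {
      expect_equal(v0$v, 0)  # two-cell carries through-flow at the centre
    } else {
      expect_equal(abs(v0$u) + abs(v0$v), 0)
    }
  }
})

test_that("four-cell velocities match the hand-differentiated streamfunction", {
  # psi = eps*x*y*(1 - r^2/R^2) gives u = eps*x*(1 - (x^2+3y^2)/R^2),
  # v = -eps*y*(1 - (3x^2+y^2)/R^2)
  f <- flowField("four_cell_bounded", strainRate = 1, dropletRadius = 1)
  v <- velocityAt(f, 0.5, 0)
  expect_equal(v$u, 0.5 * (1 - 0.25))
  expect_equal(v$v, 0)
  v <- velocityAt(f, 0, 0.5)
  expect_equal(v$u, 0)
  expect_equal(v$v, -0.5 * (1 - 0.25))
  v <- velocityAt(f, 0.3, -0.2)
  expect_equal(v$u, 0.3 * (1 - (0.09 + 3 * 0.04)))
  expect_equal(v$v, 0.2 * (1 - (3 * 0.09 + 0.04)))
  expect_error(velocityAt(f, 1.2, 0), "outside")
})

test_that("four-cell flow reduces to pure strain near the centre", {
  f4 <- flowField("four_cell_bounded", strainRate = 2, dropletRadius = 1)
  relErr <- function(rho) {
    x <- rho * cos(0.7); y <- rho * sin(0.7)
    v <- velocityAt(f4, x, y)
    sqrt((v$u - 2 * x)^2 + (v$v + 2 * y)^2) / sqrt((2 * x)^2 + (2 * y)^2)
  }
  errs <- vapply(c(0.1, 0.01, 0.001), relErr, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-5)
})

test_that("no-penetration holds on the droplet boundary", {
  for (p in c("one_cell", "two_cell", "four_cell_bounded")) {
    f <- flowField(p, strainRate = 1.3, dropletRadius = 2e-3)
    phi <- seq(0, 2 * pi, length.out = 37)
    x <- 2e-3 * cos(phi); y <- 2e-3 * sin(phi)
    v <- velocityAt(f, x, y)
    ur <- polarComponents(v$u, v$v, phi)$ur
    expect_lt(max(abs(ur)), 1e-15)
  }
})

test_that("polar decomposition is the stated rotation and preserves norm", {
  p <- polarComponents(1, 0, 0)
  expect_equal(c(p$ur, p$utheta), c(1, 0))
  p <- polarComponents(1, 0, pi / 2)
  expect_equal(c(p$ur, p$utheta), c(0, -1))
  # circumferential component of pure strain: u_theta = -eps*r*sin(2*phi)
  f <- flowField("pure_strain", strainRate = 1.7)
  phi <- seq(0.1, 2 * pi, length.out = 25)
  r <- 0.8
  v <- velocityAt(f, r * cos(phi), r * sin(phi))
  p <- polarComponents(v$u, v$v, phi)
  expect_equal(p$utheta, -1.7 * r * sin(2 * phi))
  # norm preservation, random vectors and angles
  set.seed(42)
  for (i in 1:50) {
    u <- rnorm(1); v2 <- rnorm(1); a <- runif(1, -10, 10)
    p <- polarComponents(u, v2, a)
    expect_equal(p$ur^2 + p$utheta^2, u^2 + v2^2)
  }
})

test_that("sampled grids reproduce the analytic field and its structure", {
  f <- flowField("pure_strain", strainRate = 3, dropletRadius = 1)
  g <- sampleGrid(f, 16)
  xmat <- outer(g@x, rep(1, 16))
  expect_equal(g@u, 3 * xmat)
  # single-signed vorticity for the one-cell pattern (numerical curl)
  g1 <- sampleGrid(flowField("one_cell", 1, 1), 64)
  h <- g1@x[2] - g1@x[1]
  n <- 64
  curl <- (g1@v[3:n, 2:(n - 1)] - g1@v[1:(n - 2), 2:(n - 1)]) / (2 * h) -
          (g1@u[2:(n - 1), 3:n] - g1@u[2:(n - 1), 1:(n - 2)]) / (2 * h)
  inside <- g1@mask[2:(n - 1), 2:(n - 1)]
  expect_true(all(curl[inside] > 0))
  expect_error(sampleGrid(f, 4), "at least 8")
})

test_that("numerical divergence of streamfunction fields vanishes with resolution", {
  maxDiv <- function(pattern, n) {
    g <- sampleGrid(flowField(pattern, 1, 1), n)
    h <- g@x[2] - g@x[1]
    div <- (g@u[3:n, 2:(n - 1)] - g@u[1:(n - 2), 2:(n - 1)]) / (2 * h) +
           (g@v[2:(n - 1), 3:n] - g@v[2:(n - 1), 1:(n - 2)]) / (2 * h)
    scale <- max(abs(g@u), abs(g@v))
    max(abs(div[g@mask[2:(n - 1), 2:(n - 1)]])) / scale
  }
  for (p in c("one_cell", "two_cell", "four_cell_bounded")) {
    d64 <- maxDiv(p, 64)
    d128 <- maxDiv(p, 128)
    # at least first-order convergence (polynomial fields are near-exact)
    expect_lt(d128, max(d64 / 2, 1e-10))
  }
})

test_that("recirculation-cell counting identifies each pattern", {
  expect_equal(classifyPattern(sampleGrid(flowField("one_cell", 1, 1), 64)),
               list(label = "one_cell", nCells = 1L))
  expect_equal(classifyPattern(sampleGrid(flowField("two_cell", 1, 1), 64)),
               list(label = "two_cell", nCells = 2L))
  expect_equal(classifyPattern(
    sampleGrid(flowField("four_cell_bounded", 1, 1), 64)),
    list(label = "four_cell", nCells = 4L))
  # white-noise velocities are not a recirculation pattern
  set.seed(11)
  x <- seq(-1, 1, length.out = 48)
  g <- new("VelocityGrid", x = x, y = x,
           u = matrix(rnorm(48^2), 48), v = matrix(rnorm(48^2), 48),
           mask = matrix(TRUE, 48, 48), meta = list())
  cls <- classifyPattern(g)
  expect_equal(cls$label, "random")
  expect_false(cls$nCells %in% c(1L, 2L, 4L))
  # degenerate near-zero field
  g0 <- new("VelocityGrid", x = x, y = x,
            u = matrix(0, 48, 48), v = matrix(0, 48, 48),
            mask = matrix(TRUE, 48, 48), meta = list())
  expect_equal(classifyPattern(g0), list(label = "random", nCells = 0L))
  expect_error(classifyPattern(sampleGrid(flowField("one_cell", 1, 1), 16)),
               "32")
})

test_that("velocity grids round-trip through CSV plus JSON sidecar", {
  g <- sampleGrid(flowField("two_cell", 1.5, 2e-3), 32)
  path <- file.path(withr::local_tempdir(), "grid.csv")
  writeVelocityGrid(g, path)
  g2 <- readVelocityGrid(path)
  expect_equal(g2@u, g@u)
  expect_equal(g2@v, g@v)
  expect_equal(g2@mask, g@mask)
  expect_equal(g2@meta$pattern, "two_cell")
  expect_equal(g2@meta$strain_rate, 1.5)
})
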