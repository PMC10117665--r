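#' Construct an in-droplet flow field
#'
#' The four recirculating patterns observed in the vibrating droplet are
#' represented by closed-form planar velocity fields. \code{pure_strain} is
#' the straining simplification \eqn{(u, v) = (\dot\epsilon x, -\dot\epsilon y)}
#' with a stagnation point at the centre. The bounded patterns are defined
#' by streamfunctions on the droplet disk of radius R (velocities
#' \eqn{u = \partial\psi/\partial y}, \eqn{v = -\partial\psi/\partial x}):
#' \describe{
#'   \item{one_cell}{\eqn{\psi = (\dot\epsilon/2)(R^2 - r^2)} — rigid
#'     rotation, a single recirculation cell with uniform vorticity
#'     \eqn{2\dot\epsilon}.}
#'   \item{two_cell}{\eqn{\psi = \dot\epsilon R y (1 - r^2/R^2)} — two
#'     counter-rotating cells stacked along y.}
#'   \item{four_cell_bounded}{\eqn{\psi = \dot\epsilon x y (1 - r^2/R^2)} —
#'     one cell per quadrant; near the centre (\eqn{r \ll R}) this reduces
#'     exactly to the pure straining flow.}
#' }
#' All bounded patterns have zero radial velocity on the droplet boundary
#' r = R (no penetration). With \code{strainRate > 0} the outward-flow
#' ("source") axis of the four-cell pattern is x and the inward-flow axis
#' is y; angles are measured counterclockwise from +x.
#'
#' @param pattern one of \code{"pure_strain"}, \code{"one_cell"},
#'   \code{"two_cell"}, \code{"four_cell_bounded"}.
#' @param strainRate strain-rate amplitude (1/s).
#' @param dropletRadius droplet radius R (m); ignored for pure_strain.
#' @param center droplet centre (x, y) in metres.
#' @return a [FlowField-class] object.
#' @examples
#' f <- flowField("four_cell_bounded", strainRate = 1, dropletRadius = 6e-3)
#' velocityAt(f, 1e-3, 0)
#' @export
flowField <- function(pattern = c("pure_strain", "one_cell", "two_cell",
                                  "four_cell_bounded"),
                      strainRate = 1, dropletRadius = 6e-3,
                      center = c(0, 0)) {
  pattern <- match.arg(pattern)
  new("FlowField", pattern = pattern, strainRate = as.numeric(strainRate),
      dropletRadius = as.numeric(dropletRadius), center = as.numeric(center))
}

# velocity formulas, no domain check; x, y relative to droplet centre
.velocityRaw <- function(pattern, eps, R, x, y) {
  switch(pattern,
    pure_strain = list(u = eps * x, v = -eps * y),
    one_cell = list(u = -eps * y, v = eps * x),
    two_cell = list(u = eps * R * (1 - (x^2 + 3 * y^2) / R^2),
                    v = 2 * eps * x * y / R),
    four_cell_bounded = list(u = eps * x * (1 - (x^2 + 3 * y^2) / R^2),
                             v = -eps * y * (1 - (3 * x^2 + y^2) / R^2)),
    stop("unknown pattern: ", pattern))
}

#' Evaluate the velocity of a flow field at a point
#'
#' @param field a [FlowField-class].
#' @param x,y point coordinates (m); vectors of equal length are accepted.
#' @return list with numeric components \code{u} and \code{v} (m/s).
#' @details For bounded patterns the point must lie inside the droplet disk;
#'   points outside raise an error.
#' @export
velocityAt <- function(field, x, y) {
  stopifnot(is(field, "FlowField"))
  xr <- x - field@center[1]
  yr <- y - field@center[2]
  if (field@pattern != "pure_strain") {
    r2 <- xr^2 + yr^2
    if (any(r2 > field@dropletRadius^2 * (1 + 1e-12)))
      stop("point outside the droplet for bounded pattern '",
           field@pattern, "'", call. = FALSE)
  }
  .velocityRaw(field@pattern, field@strainRate, field@dropletRadius, xr, yr)
}

#' Polar components of a planar velocity vector
#'
#' Rotates a Cartesian velocity (u, v) into the radial / circumferential
#' frame at polar angle \code{phi}:
#' \eqn{u_r = u\cos\phi + v\sin\phi}, \eqn{u_\theta = -u\sin\phi + v\cos\phi}.
#' The transformation is an isometry, so the vector norm is preserved.
#'
#' @param u,v Cartesian velocity components (m/s).
#' @param phi polar angle of the evaluation point (radians).
#' @return list with components \code{ur} and \code{utheta}.
#' @export
polarComponents <- function(u, v, phi) {
  list(ur = u * cos(phi) + v * sin(phi),
       utheta = -u * sin(phi) + v * cos(phi))
}

#' Sample a flow field on a uniform grid
#'
#' Evaluates the field on an \code{nPerAxis} x \code{nPerAxis} grid spanning
#' the droplet bounding box (for pure_strain, the box of half-width
#' \code{dropletRadius}). The analytic formulas extend smoothly beyond the
#' disk, so velocities are stored at every node and \code{mask} marks the
#' nodes inside the droplet.
#'
#' @param field a [FlowField-class].
#' @param nPerAxis nodes per axis, at least 8.
#' @return a [VelocityGrid-class].
#' @export
sampleGrid <- function(field, nPerAxis = 64) {
  stopifnot(is(field, "FlowField"))
  if (nPerAxis < 8) stop("nPerAxis must be at least 8")
  R <- field@dropletRadius
  x <- seq(field@center[1] - R, field@center[1] + R, length.out = nPerAxis)
  y <- seq(field@center[2] - R, field@center[2] + R, length.out = nPerAxis)
  xr <- outer(x - field@center[1], rep(1, nPerAxis))
  yr <- outer(rep(1, nPerAxis), y - field@center[2])
  vel <- .velocityRaw(field@pattern, field@strainRate, R, xr, yr)
  mask <- if (field@pattern == "pure_strain") {
    matrix(TRUE, nPerAxis, nPerAxis)
  } else {
    xr^2 + yr^2 <= R^2 * (1 + 1e-12)
  }
  new("VelocityGrid", x = x, y = y, u = vel$u, v = vel$v, mask = mask,
      meta = list(pattern = field@pattern, strain_rate = field@strainRate,
                  droplet_radius = R, n_per_axis = as.integer(nPerAxis)))
}

# reconstruct the streamfunction on the full rectangle by trapezoidal path
# integration: psi along the first row from -v dx, then up each column from
# u dy; averaged with the transposed path for robustness on noisy grids.
.streamFunction <- function(x, y, u, v) {
  cumtrap <- function(f, h) {
    n <- length(f)
    if (n == 1L) return(0)
    c(0, cumsum((f[-n] + f[-1]) / 2 * h))
  }
  dx <- if (length(x) > 1) x[2] - x[1] else 1
  dy <- if (length(y) > 1) y[2] - y[1] else 1
  nx <- length(x); ny <- length(y)
  # path A: -int v dx along y = y[1], then + int u dy up each column
  row1 <- -cumtrap(v[, 1], dx)
  psiA <- matrix(0, nx, ny)
  for (i in seq_len(nx)) psiA[i, ] <- row1[i] + cumtrap(u[i, ], dy)
  # path B: + int u dy along x = x[1], then - int v dx along each row
  col1 <- cumtrap(u[1, ], dy)
  psiB <- matrix(0, nx, ny)
  for (j in seq_len(ny)) psiB[, j] <- col1[j] - cumtrap(v[, j], dx)
  (psiA + psiB) / 2
}

#' Count recirculation cells and classify a velocity grid
#'
#' Reconstructs the streamfunction by trapezoidal path integration of the
#' sampled velocities, smooths it with a Gaussian of width
#' \code{smoothSigma} grid cells, and
#' counts strict local extrema (over the 8-neighbourhood) at nodes whose
#' full neighbourhood lies inside the droplet mask. Each recirculation cell
#' contributes exactly one streamfunction extremum, so the count maps to
#' the pattern label: 1 cell, 2 cells, 4 cells, anything else
#' \code{"random"}. A near-zero field (all speeds below \code{degenerateTol})
#' is labelled random with 0 cells.
#'
#' @param grid a [VelocityGrid-class] with at least 32 nodes per axis.
#' @param degenerateTol speed (m/s) below which the field is degenerate.
#' @param smoothSigma Gaussian smoothing width in grid cells; 1.5 is wide
#'   enough to suppress the bin-to-bin noise of tracer-derived grids while
#'   leaving analytic fields untouched.
#' @return list with \code{label} and \code{nCells}.
#' @export
classifyPattern <- function(grid, degenerateTol = 1e-12,
                            smoothSigma = 1.5) {
  stopifnot(is(grid, "VelocityGrid"))
  if (length(grid@x) < 32 || length(grid@y) < 32)
    stop("classifyPattern needs at least 32 nodes per axis")
  u <- grid@u; v <- grid@v
  u[!is.finite(u)] <- 0
  v[!is.finite(v)] <- 0
  if (max(abs(u[grid@mask]), abs(v[grid@mask]), 0) < degenerateTol)
    return(list(label = "random", nCells = 0L))
  nx <- length(grid@x); ny <- length(grid@y)
  m <- grid@mask
  # sparsely sampled grids (e.g. from tracer tracks) have interior holes;
  # fill them by repeated neighbour averaging over the disk hull spanned
  # by the sampled nodes, so the extremum count sees a connected field
  cx <- mean(range(grid@x)); cy <- mean(range(grid@y))
  r2 <- outer((grid@x - cx)^2, rep(1, ny)) +
        outer(rep(1, nx), (grid@y - cy)^2)
  hull <- r2 <= max(r2[m]) * (1 + 1e-12)
  if (any(hull & !m)) {
    shiftF <- function(mat, di, dj, fill) {
      out <- matrix(fill, nx, ny)
      ri <- seq_len(nx) + di; cj <- seq_len(ny) + dj
      vi <- which(ri >= 1 & ri <= nx); vj <- which(cj >= 1 & cj <= ny)
      out[vi, vj] <- mat[ri[vi], cj[vj]]
      out
    }
    filled <- m
    repeat {
      usum <- matrix(0, nx, ny); vsum <- usum; cnt <- usum
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        fF <- shiftF(filled, di, dj, FALSE)
        usum <- usum + shiftF(u * filled, di, dj, 0)
        vsum <- vsum + shiftF(v * filled, di, dj, 0)
        cnt <- cnt + fF
      }
      newly <- hull & !filled & cnt > 0
      if (!any(newly)) break
      u[newly] <- usum[newly] / cnt[newly]
      v[newly] <- vsum[newly] / cnt[newly]
      filled <- filled | newly
    }
    m <- filled
  }
  psi <- .streamFunction(grid@x, grid@y, u, v)
  psi <- .convolve2(psi, .gaussKernel(smoothSigma))
  # interior nodes whose full 3x3 neighbourhood is masked-in
  ok <- matrix(FALSE, nx, ny)
  ok[2:(nx - 1), 2:(ny - 1)] <- TRUE
  shift <- function(mat, di, dj, fill) {
    out <- matrix(fill, nx, ny)
    ri <- seq_len(nx) + di; cj <- seq_len(ny) + dj
    vi <- which(ri >= 1 & ri <= nx); vj <- which(cj >= 1 & cj <= ny)
    out[vi, vj] <- mat[ri[vi], cj[vj]]
    out
  }
  nbMax <- matrix(-Inf, nx, ny); nbMin <- matrix(Inf, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    ok <- ok & shift(m, di, dj, FALSE)
    if (di == 0 && dj == 0) next
    nbMax <- pmax(nbMax, shift(psi, di, dj, -Inf))
    nbMin <- pmin(nbMin, shift(psi, di, dj, Inf))
  }
  # plateau-tolerant extrema: a node must tie the extreme of its
  # neighbourhood and strictly beat at least one neighbour, so symmetric
  # peaks straddling grid nodes count and flat regions do not; adjacent
  # candidate nodes are merged into one cell each
  tol <- 1e-8 * max(diff(range(psi[ok])), .Machine$double.xmin)
  candMax <- psi >= nbMax - tol & psi > nbMin + tol
  candMin <- psi <= nbMin + tol & psi < nbMax - tol
  countComponents <- function(cand) {
    if (!any(cand & ok)) return(0L)
    lab <- .label8(cand)
    length(unique(lab[cand & ok]))
  }
  nCells <- countComponents(candMax) + countComponents(candMin)
  label <- switch(as.character(nCells), "1" = "one_cell", "2" = "two_cell",
                  "4" = "four_cell", "random")
  list(label = label, nCells = nCells)
}

#' Write / read a velocity grid as CSV plus JSON sidecar
#'
#' Long-format CSV with columns x, y, u, v, inside; metadata (pattern,
#' strain rate, droplet radius, grid size, free-text notes such as the
#' driving-frequency band) go to \code{<path>.json}.
#'
#' @param grid a [VelocityGrid-class].
#' @param path CSV file path; the sidecar is written to \code{<path>.json}.
#' @return \code{writeVelocityGrid} returns \code{path} invisibly;
#'   \code{readVelocityGrid} returns a [VelocityGrid-class].
#' @export
writeVelocityGrid <- function(grid, path) {
  stopifnot(is(grid, "VelocityGrid"))
  df <- data.frame(
    x = rep(grid@x, times = length(grid@y)),
    y = rep(grid@y, each = length(grid@x)),
    u = as.vector(grid@u), v = as.vector(grid@v),
    inside = as.integer(as.vector(grid@mask)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(grid@meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVelocityGrid
#' @export
readVelocityGrid <- function(path) {
  df <- utils::read.csv(path)
  x <- sort(unique(df$x)); y <- sort(unique(df$y))
  idx <- cbind(match(df$x, x), match(df$y, y))
  u <- matrix(NA_real_, length(x), length(y)); v <- u
  mask <- matrix(FALSE, length(x), length(y))
  u[idx] <- df$u; v[idx] <- df$v; mask[idx] <- df$inside > 0
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new("VelocityGrid", x = x, y = y, u = u, v = v, mask = mask,
      meta = as.list(meta))
}
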