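# Internal angle helpers. Degrees at user-facing interfaces, radians inside.

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

# wrap degrees to [0, 360)
.wrap360 <- function(d) ((d %% 360) + 360) %% 360

# signed circular distance a - b in degrees, in (-180, 180]
.circDiffDeg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# unsigned circular distance in degrees, in [0, 180]
.circDistDeg <- function(a, b) abs(.circDiffDeg(a, b))

# run code with a temporary RNG seed, restoring global state afterwards
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(force(code))
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

.assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be nonnegative", name), call. = FALSE)
  invisible(x)
}

# 2D convolution with a small odd-sized kernel, replicated edges
.convolve2 <- function(m, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr + 2L * kr) - kr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * kc) - kc, 1L), nc)
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(kernel)))
    for (j in seq_len(ncol(kernel)))
      out <- out + kernel[i, j] *
        pad[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc), drop = FALSE]
  out
}

# normalised Gaussian kernel, sigma in grid cells, radius 3*sigma
.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}
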