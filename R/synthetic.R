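#' Specification of a synthetic mobility cohort
#'
#' Describes a cohort of simulated fish across the three mobility classes:
#' \describe{
#'   \item{typeI}{untreated, full self-righting activity (default 5 times
#'     the strain rate, well above the critical activity 2 strain rates).}
#'   \item{typeII}{anesthetised or motor-deficient, zero activity; the
#'     flow pins these fish to the sink axis. Lipin-1-deficient fish are
#'     parameterised identically but may carry their own label.}
#'   \item{typeIII}{recovering: activity ramps linearly from 0 to the
#'     type-I level over \code{rampDuration} (default 20 simulated
#'     minutes).}
#' }
#' Each fish gets a distinct seed derived from \code{baseSeed} and an
#' initial heading drawn from its seed; a fish's preferred upstream
#' heading (90 or 270 degrees) is whichever is closer to its initial
#' heading.
#'
#' @param nPerClass fish per class (single count or named vector over
#'   typeI/typeII/typeIII).
#' @param strainRate strain rate of the trapping flow (1/s).
#' @param activityHigh type-I activity amplitude (1/s).
#' @param rotNoise rotational diffusivity (rad^2/s).
#' @param duration observation window for types I and II (s); default
#'   300 s, a 5-minute recording.
#' @param rampDuration type-III ramp and observation duration (s).
#' @param dt integration step (s).
#' @param baseSeed integer seed from which per-fish seeds are derived.
#' @return list with class \code{"cohortSpec"}.
#' @export
cohortSpec <- function(nPerClass = 5, strainRate = 1,
                       activityHigh = 5 * strainRate, rotNoise = 0.05,
                       duration = 300, rampDuration = 1200, dt = 0.02,
                       baseSeed = 1) {
  if (length(nPerClass) == 1L)
    nPerClass <- c(typeI = nPerClass, typeII = nPerClass,
                   typeIII = nPerClass)
  stopifnot(all(nPerClass >= 1),
            all(names(nPerClass) %in% c("typeI", "typeII", "typeIII")))
  structure(list(nPerClass = nPerClass, strainRate = strainRate,
                 activityHigh = activityHigh, rotNoise = rotNoise,
                 duration = duration, rampDuration = rampDuration,
                 dt = dt, baseSeed = baseSeed),
            class = "cohortSpec")
}

#' Generate a synthetic cohort of orientation trajectories
#'
#' Simulates every fish of a [cohortSpec()] with its class parameters via
#' [simulateSwimmer()]. Type-III fish start near the sink axis (they begin
#' anesthetised and trapped) and carry a linear activity ramp; ground
#' truth (class, activity, seed) is attached to each trajectory. Output is
#' fully determined by the spec argument and its seeds.
#'
#' @param spec a [cohortSpec()].
#' @return list of entries, each with elements \code{traj}
#'   ([OrientationTrajectory-class]), \code{type}, \code{activity} (final
#'   amplitude), and \code{seed}.
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  out <- list()
  fishIdx <- 0L
  for (type in c("typeI", "typeII", "typeIII")) {
    nf <- spec$nPerClass[[type]]
    if (is.null(nf) || is.na(nf)) next
    for (i in seq_len(nf)) {
      fishIdx <- fishIdx + 1L
      seed <- spec$baseSeed + 977L * fishIdx
      theta0 <- .withSeed(seed, {
        if (type == "typeIII") {
          # starts pinned at the sink, either end, within the ~0+/-10 band
          .wrap360(sample(c(0, 180), 1) + stats::runif(1, -10, 10))
        } else stats::runif(1, 0, 360)
      })
      goalDeg <- if (.circDistDeg(theta0, 90) <= .circDistDeg(theta0, 270))
        90 else 270
      activity <- switch(type,
        typeI = spec$activityHigh,
        typeII = 0,
        typeIII = local({
          Ahi <- spec$activityHigh; Tr <- spec$rampDuration
          function(t) Ahi * min(t / Tr, 1)
        }))
      duration <- if (type == "typeIII") spec$rampDuration else spec$duration
      traj <- simulateSwimmer(activity = activity, goalDeg = goalDeg,
                              rotNoise = spec$rotNoise,
                              strainRate = spec$strainRate, dt = spec$dt,
                              duration = duration, theta0Deg = theta0,
                              seed = seed + 1L)
      traj@meta$type <- type
      traj@meta$fish_id <- fishIdx
      out[[fishIdx]] <- list(traj = traj, type = type,
                             activity = if (type == "typeII") 0
                                        else spec$activityHigh,
                             seed = seed)
    }
  }
  out
}

#' Specification of a synthetic fluorescence scene
#'
#' Emulates the tracer-particle (and optionally single-fish) recordings:
#' fluorescent tracers advected by an in-droplet flow, imaged as Gaussian
#' spots with additive sensor noise. Defaults follow the experimental
#' geometry: 12 mm droplet, 20 micrometre pixels, 30 fps for particle
#' scenes.
#'
#' @param pattern flow pattern (see [flowField()]).
#' @param strainRate strain rate (1/s).
#' @param dropletRadius droplet radius (m).
#' @param nParticles number of tracer particles.
#' @param psfSigmaPx Gaussian spot width (px).
#' @param noiseSigma additive Gaussian intensity noise sd (spot peak = 1,
#'   so SNR = 1/noiseSigma).
#' @param minSepPx minimum initial separation between tracers (px);
#'   tracers closer than about two spot widths merge into one blob, so
#'   seeding keeps them resolvable.
#' @param frameRate frames per second.
#' @param duration scene duration (s).
#' @param pxScale metres per pixel.
#' @param seed RNG seed.
#' @return list with class \code{"sceneSpec"}.
#' @export
sceneSpec <- function(pattern = "four_cell_bounded", strainRate = 1,
                      dropletRadius = 6e-3, nParticles = 30,
                      psfSigmaPx = 1.2, noiseSigma = 0.02, frameRate = 30,
                      duration = 2, pxScale = 2e-5, seed = 1,
                      minSepPx = 6) {
  stopifnot(nParticles >= 0, psfSigmaPx > 0)
  structure(list(pattern = pattern, strainRate = strainRate,
                 dropletRadius = dropletRadius, nParticles = nParticles,
                 psfSigmaPx = psfSigmaPx, noiseSigma = noiseSigma,
                 frameRate = frameRate, duration = duration,
                 pxScale = pxScale, seed = seed, minSepPx = minSepPx),
            class = "sceneSpec")
}

# add one Gaussian spot to an (H, W) frame; x/y in 0-based px coordinates
.addSpot <- function(frame, x, y, sigma, amp) {
  H <- nrow(frame); W <- ncol(frame)
  r <- ceiling(4 * sigma)
  cs <- max(1L, floor(x) - r + 1L):min(W, ceiling(x) + r + 1L)
  rs <- max(1L, floor(y) - r + 1L):min(H, ceiling(y) + r + 1L)
  if (!length(cs) || !length(rs)) return(frame)
  gx <- exp(-((cs - 1) - x)^2 / (2 * sigma^2))
  gy <- exp(-((rs - 1) - y)^2 / (2 * sigma^2))
  frame[rs, cs] <- frame[rs, cs] + amp * outer(gy, gx)
  frame
}

#' Render a synthetic tracer/fish scene
#'
#' Initialises tracers uniformly inside the droplet, advects them with
#' two-stage Runge--Kutta (midpoint) steps of the flow field, and renders
#' each as a Gaussian spot. An optional fish is drawn at the droplet
#' centre as a chain of Gaussian blobs along its body axis with a brighter
#' head end (so the head can be told from the tail by the intensity
#' asymmetry); its per-frame orientation is interpolated from the supplied
#' trajectory. Seeded Gaussian noise is added last. Ground-truth particle
#' positions and fish angles are returned alongside the stack.
#'
#' @param spec a [sceneSpec()].
#' @param fish optional [OrientationTrajectory-class] for a fish at the
#'   droplet centre.
#' @param fishLength fish body length (m), used only when \code{fish} is
#'   given.
#' @return list with \code{stack} ([FrameStack-class]), \code{truth}
#'   (data.frame: frame, id, x_px, y_px), and \code{fishTruth}
#'   (data.frame: frame, angle_deg; NULL without a fish).
#' @export
renderScene <- function(spec = sceneSpec(), fish = NULL,
                        fishLength = 4e-3) {
  stopifnot(inherits(spec, "sceneSpec"))
  field <- flowField(spec$pattern, spec$strainRate, spec$dropletRadius)
  R <- spec$dropletRadius
  Wpx <- 2L * ceiling(R / spec$pxScale) + 9L
  Hpx <- Wpx
  nT <- max(2L, round(spec$duration * spec$frameRate))
  dt <- 1 / spec$frameRate
  toPx <- function(xm, ym) list(x = (Wpx - 1) / 2 + xm / spec$pxScale,
                                y = (Hpx - 1) / 2 - ym / spec$pxScale)
  frames <- array(0, dim = c(Hpx, Wpx, nT))
  truthRows <- vector("list", nT)
  .withSeed(spec$seed, {
    # uniform in the disk, margin so spots stay inside the image
    n <- spec$nParticles
    if (n > 0) {
      minSep <- spec$minSepPx * spec$pxScale
      px <- py <- numeric(0)
      tries <- 0L
      while (length(px) < n && tries < 10000L) {
        tries <- tries + 1L
        rr <- 0.85 * R * sqrt(stats::runif(1))
        aa <- stats::runif(1, 0, 2 * pi)
        cx <- rr * cos(aa); cy <- rr * sin(aa)
        if (!length(px) || min((px - cx)^2 + (py - cy)^2) >= minSep^2) {
          px <- c(px, cx); py <- c(py, cy)
        }
      }
      if (length(px) < n)
        stop("could not place ", n, " tracers at the requested separation")
    } else px <- py <- numeric(0)
    nSub <- 4L
    hdt <- dt / nSub
    for (f in seq_len(nT)) {
      fr <- frames[, , f]
      if (n > 0) {
        pc <- toPx(px, py)
        for (k in seq_len(n))
          fr <- .addSpot(fr, pc$x[k], pc$y[k], spec$psfSigmaPx, 1)
        truthRows[[f]] <- data.frame(frame = f, id = seq_len(n),
                                     x_px = pc$x, y_px = pc$y)
        for (s in seq_len(nSub)) {  # midpoint RK2 advection
          v1 <- .velocityRaw(spec$pattern, spec$strainRate, R, px, py)
          xm <- px + 0.5 * hdt * v1$u; ym <- py + 0.5 * hdt * v1$v
          v2 <- .velocityRaw(spec$pattern, spec$strainRate, R, xm, ym)
          px <- px + hdt * v2$u; py <- py + hdt * v2$v
          rad <- sqrt(px^2 + py^2)
          out <- rad > 0.98 * R
          if (any(out)) {
            px[out] <- px[out] * 0.98 * R / rad[out]
            py[out] <- py[out] * 0.98 * R / rad[out]
          }
        }
      }
      frames[, , f] <- fr
    }
    fishTruth <- NULL
    if (!is.null(fish)) {
      stopifnot(is(fish, "OrientationTrajectory"))
      tFrame <- (seq_len(nT) - 1) * dt
      angles <- vapply(tFrame, function(t) {
        i <- which.min(abs(fish@times - t))
        fish@anglesDeg[i]
      }, numeric(1))
      Lpx <- fishLength / spec$pxScale
      srel <- seq(-0.5, 0.5, length.out = 15)
      amps <- seq(0.6, 1.3, length.out = 15)  # brighter toward the head
      sigmaBody <- Lpx / 14
      ctr <- toPx(0, 0)
      for (f in seq_len(nT)) {
        th <- .deg2rad(angles[f])
        fr <- frames[, , f]
        for (k in seq_along(srel)) {
          # physical heading th; image y is flipped
          bx <- ctr$x + srel[k] * Lpx * cos(th)
          by <- ctr$y - srel[k] * Lpx * sin(th)
          fr <- .addSpot(fr, bx, by, sigmaBody, amps[k])
        }
        frames[, , f] <- fr
      }
      fishTruth <- data.frame(frame = seq_len(nT), angle_deg = angles)
    }
    if (spec$noiseSigma > 0) {
      frames <- frames + stats::rnorm(length(frames), 0, spec$noiseSigma)
      frames[frames < 0] <- 0
    }
  })
  truth <- if (spec$nParticles > 0) do.call(rbind, truthRows) else
    data.frame(frame = integer(0), id = integer(0), x_px = numeric(0),
               y_px = numeric(0))
  list(stack = frameStack(frames, frameRate = spec$frameRate,
                          pxScale = spec$pxScale),
       truth = truth, fishTruth = fishTruth)
}

#' Generate a no-flow random-walk track
#'
#' Seeded 2D Gaussian random walk in physical units, the synthetic
#' stand-in for a fish wandering a miniature pool without flow; used for
#' exercising the MSD analysis. With a finite \code{poolRadius} the walk
#' reflects off the circular wall, which makes the MSD saturate at long
#' lags.
#'
#' @param nSteps number of steps (track has nSteps + 1 samples).
#' @param stepSigma per-axis step standard deviation (m).
#' @param dt sampling interval (s).
#' @param seed RNG seed.
#' @param poolRadius reflecting-wall radius (m), or NULL for an unbounded
#'   walk.
#' @return data.frame with columns track_id, frame, time_s, x_m, y_m.
#' @export
generatePoolWalk <- function(nSteps, stepSigma = 1e-4, dt = 0.05, seed = 1,
                             poolRadius = NULL) {
  if (nSteps < 2) stop("nSteps must be at least 2")
  .withSeed(seed, {
    dx <- stats::rnorm(nSteps, 0, stepSigma)
    dy <- stats::rnorm(nSteps, 0, stepSigma)
    x <- numeric(nSteps + 1); y <- numeric(nSteps + 1)
    for (k in seq_len(nSteps)) {
      x[k + 1] <- x[k] + dx[k]
      y[k + 1] <- y[k] + dy[k]
      if (!is.null(poolRadius)) {
        r <- sqrt(x[k + 1]^2 + y[k + 1]^2)
        if (r > poolRadius) {  # radial reflection off the wall
          scale <- (2 * poolRadius - r) / r
          x[k + 1] <- x[k + 1] * scale
          y[k + 1] <- y[k + 1] * scale
        }
      }
    }
    data.frame(track_id = 1L, frame = 0:nSteps, time_s = dt * (0:nSteps),
               x_m = x, y_m = y)
  })
}
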