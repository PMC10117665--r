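#' Passive rotational drift of a rod at the stagnation point
#'
#' Balancing the viscous torque against rotational drag (both taken over
#' the same rod domain, so all material constants cancel) gives the
#' overdamped relaxation law \eqn{\dot\theta = -\dot\epsilon \sin 2\theta}.
#' Its fixed points coincide with the torque equilibria: 0/180 deg (sink
#' axis, stable for positive strain rate) and 90/270 deg (source axis,
#' unstable).
#'
#' @param theta orientation (radians); vectorised.
#' @param strainRate strain rate (1/s).
#' @return d theta / dt in rad/s.
#' @export
passiveDrift <- function(theta, strainRate) {
  -strainRate * sin(2 * theta)
}

#' Active (self-righting) rotational drift
#'
#' Adds the minimal smooth self-righting term \eqn{A \sin(\theta_g - \theta)}
#' to the passive law, modelling a fish that steers toward the preferred
#' upstream heading \eqn{\theta_g} with angular-rate amplitude A. A = 0
#' recovers the passive rod exactly.
#'
#' @param theta orientation (radians); vectorised.
#' @param activity self-righting amplitude A (1/s), nonnegative.
#' @param goal preferred heading (radians); default pi/2, the inward-flow
#'   (source-facing) axis.
#' @param strainRate strain rate (1/s).
#' @return d theta / dt in rad/s.
#' @export
activeDrift <- function(theta, activity, goal = pi / 2, strainRate = 1) {
  if (any(activity < 0)) stop("activity must be nonnegative")
  passiveDrift(theta, strainRate) + activity * sin(goal - theta)
}

#' Critical activity for holding the source heading
#'
#' Linearising the active drift about the goal heading 90 deg gives a decay
#' rate \eqn{A - 2\dot\epsilon}: the source heading becomes linearly stable
#' when the self-righting amplitude exceeds \eqn{A_c = 2\dot\epsilon}.
#'
#' @param strainRate strain rate (1/s), positive.
#' @return the critical activity (1/s).
#' @export
criticalActivity <- function(strainRate) {
  .assertScalar(strainRate, "strainRate", positive = TRUE)
  2 * strainRate
}

#' Simulate the heading of an active swimmer in the flow trap
#'
#' Euler--Maruyama integration of the overdamped rotational Langevin
#' equation
#' \deqn{\theta_{k+1} = \theta_k + \mathrm{drift}(\theta_k, t_k)\,\Delta t
#'   + \sqrt{2 D_r \Delta t}\, z_k,}
#' with standard-normal \eqn{z_k} from the seeded generator. The fish is
#' held at the stagnation point by the trap, so only the heading evolves.
#' \code{activity} may be a single amplitude or a function of time
#' (used for recovery ramps). Identical seeds give bitwise-identical
#' trajectories; the global RNG state is restored afterwards.
#'
#' @param activity self-righting amplitude A (1/s), or a function
#'   \code{A(t)} returning the amplitude at time t.
#' @param goalDeg preferred heading (degrees), default 90.
#' @param rotNoise rotational diffusivity D_r (rad^2/s).
#' @param strainRate strain rate (1/s).
#' @param dt time step (s).
#' @param duration total simulated time (s).
#' @param theta0Deg initial heading (degrees).
#' @param seed RNG seed (integer) or NULL to use the current RNG state.
#' @return an [OrientationTrajectory-class] with samples at 0, dt, ..., T.
#' @examples
#' tr <- simulateSwimmer(activity = 5, strainRate = 1, dt = 0.01,
#'                       duration = 10, theta0Deg = 30, seed = 1)
#' tail(headingDeg(tr), 1)
#' @export
simulateSwimmer <- function(activity = 0, goalDeg = 90, rotNoise = 0.05,
                            strainRate = 1, dt = 0.01, duration = 60,
                            theta0Deg = 45, seed = NULL) {
  .assertScalar(dt, "dt", positive = TRUE)
  .assertScalar(duration, "duration", positive = TRUE)
  if (duration < dt) stop("duration must be at least dt")
  .assertScalar(rotNoise, "rotNoise", nonneg = TRUE)
  aFun <- if (is.function(activity)) activity else {
    .assertScalar(activity, "activity", nonneg = TRUE)
    function(t) activity
  }
  aMax <- max(vapply(seq(0, duration, length.out = 101), aFun, numeric(1)))
  if (dt * (abs(strainRate) + aMax) > 0.2)
    stop("dt too large for stable integration: dt * max|drift| = ",
         signif(dt * (abs(strainRate) + aMax), 3), " > 0.2 rad", call. = FALSE)
  goal <- .deg2rad(goalDeg)
  nSteps <- floor(duration / dt + 1e-9)
  theta <- numeric(nSteps + 1L)
  theta[1] <- .deg2rad(theta0Deg)
  noiseAmp <- sqrt(2 * rotNoise * dt)
  .withSeed(seed, {
    z <- if (rotNoise > 0) stats::rnorm(nSteps) else numeric(nSteps)
    for (k in seq_len(nSteps)) {
      th <- theta[k]
      drift <- -strainRate * sin(2 * th) +
        aFun((k - 1) * dt) * sin(goal - th)
      theta[k + 1L] <- th + drift * dt + noiseAmp * z[k]
    }
  })
  new("OrientationTrajectory",
      times = dt * (0:nSteps),
      anglesDeg = .wrap360(.rad2deg(theta)),
      meta = list(activity = if (is.function(activity)) "time-varying"
                  else activity,
                  goal_deg = goalDeg, rot_noise = rotNoise,
                  strain_rate = strainRate, dt = dt, duration = duration,
                  theta0_deg = theta0Deg, seed = seed))
}

#' Estimate the activity parameter from a heading trajectory
#'
#' Regresses the finite-difference angular rate on the model's drift terms.
#' With the strain rate known (default), the passive term is subtracted and
#' the self-righting amplitude is the single least-squares coefficient of
#' \eqn{\sin(\theta_g - \theta)}; with \code{estimateStrain = TRUE} both
#' coefficients are co-estimated. The estimate is clipped at zero (the
#' amplitude is a rate, not a signed quantity); the reported standard error
#' is the unclipped regression SE.
#'
#' @param traj an [OrientationTrajectory-class] with at least 100 samples,
#'   uniformly sampled.
#' @param strainRate strain rate used in the simulation/experiment (1/s).
#' @param goalDeg preferred heading (degrees).
#' @param estimateStrain co-estimate the strain coefficient instead of
#'   fixing it.
#' @return list with \code{activity}, \code{se}, and (when co-estimated)
#'   \code{strainRate}.
#' @export
estimateActivity <- function(traj, strainRate, goalDeg = 90,
                             estimateStrain = FALSE) {
  stopifnot(is(traj, "OrientationTrajectory"))
  n <- length(traj@times)
  if (n < 100) stop("need at least 100 samples to estimate the activity")
  dts <- diff(traj@times)
  if (diff(range(dts)) > 1e-9 * mean(dts))
    stop("trajectory must be uniformly sampled")
  dt <- mean(dts)
  th <- .deg2rad(traj@anglesDeg)
  # wrapped finite difference: step magnitudes are << pi for sane dt
  dth <- .deg2rad(.circDiffDeg(traj@anglesDeg[-1], traj@anglesDeg[-n]))
  rate <- dth / dt
  thk <- th[-n]
  goal <- .deg2rad(goalDeg)
  xAct <- sin(goal - thk)
  if (stats::sd(xAct) < 1e-10)
    stop("heading pinned at the goal: activity is unidentifiable",
         call. = FALSE)
  if (estimateStrain) {
    fit <- stats::lm(rate ~ 0 + I(-sin(2 * thk)) + xAct)
    co <- summary(fit)$coefficients
    list(activity = max(0, co[2, 1]), se = co[2, 2], strainRate = co[1, 1])
  } else {
    y <- rate + strainRate * sin(2 * thk)
    fit <- stats::lm(y ~ 0 + xAct)
    co <- summary(fit)$coefficients
    list(activity = max(0, co[1, 1]), se = co[1, 2])
  }
}

#' Write / read an orientation trajectory (CSV + JSON metadata)
#'
#' CSV columns \code{time_s}, \code{angle_deg}; simulation parameters go to
#' \code{<path>.json}.
#'
#' @param traj an [OrientationTrajectory-class].
#' @param path CSV file path.
#' @return \code{writeTrajectory} returns \code{path} invisibly;
#'   \code{readTrajectory} an [OrientationTrajectory-class].
#' @export
writeTrajectory <- function(traj, path) {
  stopifnot(is(traj, "OrientationTrajectory"))
  utils::write.csv(data.frame(time_s = traj@times,
                              angle_deg = traj@anglesDeg),
                   path, row.names = FALSE)
  meta <- traj@meta
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  df <- utils::read.csv(path)
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  new("OrientationTrajectory", times = df$time_s,
      anglesDeg = .wrap360(df$angle_deg), meta = as.list(meta))
}
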