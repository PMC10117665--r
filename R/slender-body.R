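#' Construct a slender-body geometry
#'
#' @param lengthL body length L (m). Default 4 mm, a 72 hpf larva.
#' @param radiusA cross-section radius a (m). Default 0.25 mm.
#' @return a [SlenderBody-class].
#' @examples
#' fish <- slenderBody(4e-3, 2.5e-4)
#' dragCoefficients(fish, viscosity = 1e-3)
#' @export
slenderBody <- function(lengthL = 4e-3, radiusA = 2.5e-4) {
  new("SlenderBody", lengthL = as.numeric(lengthL),
      radiusA = as.numeric(radiusA))
}

#' Slender-body drag coefficients
#'
#' For a rod of length L and cross-section radius a in a fluid of dynamic
#' viscosity mu, the resistive-force coefficients per unit length are
#' \deqn{c_\parallel = 4\pi\mu/c, \qquad c_\perp = 8\pi\mu/c,}
#' with the dimensionless correction \eqn{c = 2\ln(L/a) - 1}. The
#' perpendicular coefficient is exactly twice the parallel one. Geometries
#' with \eqn{L/a \le e} (where c would drop to or below 1) are rejected as
#' outside slender-body validity.
#'
#' @param body a [SlenderBody-class].
#' @param viscosity dynamic viscosity mu (Pa s); water is about 1e-3.
#' @return a [DragCoefficients-class].
#' @export
dragCoefficients <- function(body, viscosity = 1e-3) {
  stopifnot(is(body, "SlenderBody"))
  .assertScalar(viscosity, "viscosity", positive = TRUE)
  cc <- 2 * log(body@lengthL / body@radiusA) - 1
  new("DragCoefficients", cCorrection = cc,
      cParallel = 4 * pi * viscosity / cc,
      cPerp = 8 * pi * viscosity / cc)
}

#' Closed-form viscous torque on a rod in the straining flow
#'
#' Torque about the rod end held at the stagnation point of the planar
#' straining flow, for a rod at orientation theta:
#' \deqn{T(\theta) = -\frac{8\pi\mu\dot\epsilon}{c}\,\frac{L^3}{3}\sin 2\theta.}
#' The prefactor corresponds to the rod occupying arc length s in [0, L]
#' from the pivot (\eqn{c_\perp \int_0^L s^2\,ds = c_\perp L^3/3}). The
#' torque is antisymmetric in theta, has period pi, and vanishes at
#' theta = pi/2 (unstable) and theta = pi (stable) — see [equilibria()].
#'
#' @param body a [SlenderBody-class].
#' @param viscosity dynamic viscosity (Pa s).
#' @param strainRate strain rate (1/s).
#' @param theta rod orientation (radians); vectorised.
#' @return torque in N m.
#' @export
torqueClosedForm <- function(body, viscosity = 1e-3, strainRate = 1, theta) {
  stopifnot(is(body, "SlenderBody"))
  .assertScalar(viscosity, "viscosity", positive = TRUE)
  .assertScalar(strainRate, "strainRate")
  cc <- 2 * log(body@lengthL / body@radiusA) - 1
  -(8 * pi * viscosity * strainRate / cc) * body@lengthL^3 / 3 * sin(2 * theta)
}

#' Viscous torque by quadrature over an arbitrary flow field
#'
#' Integrates \eqn{T = \int_0^L s\, c_\perp\, u_\theta'(s)\, ds} along the
#' rod, where \eqn{u_\theta'(s) = u_\theta(s) - \dot\theta\, s} is the
#' circumferential flow component about the pivot minus the rod's own
#' rotation. The rod spans arc length s in [0, L] from the pivot in the
#' direction theta. On the pure straining flow with the pivot at the origin
#' and \eqn{\dot\theta = 0} this reproduces [torqueClosedForm()] to
#' quadrature accuracy.
#'
#' @param body a [SlenderBody-class].
#' @param viscosity dynamic viscosity (Pa s).
#' @param field a [FlowField-class].
#' @param pivot numeric length-2, pivot position (m).
#' @param theta rod orientation (radians), scalar.
#' @param thetaDot rod rotation rate (rad/s).
#' @return torque in N m.
#' @export
torqueNumeric <- function(body, viscosity = 1e-3, field, pivot = c(0, 0),
                          theta, thetaDot = 0) {
  stopifnot(is(body, "SlenderBody"), is(field, "FlowField"))
  .assertScalar(theta, "theta"); .assertScalar(thetaDot, "thetaDot")
  L <- body@lengthL
  dirv <- c(cos(theta), sin(theta))
  if (field@pattern != "pure_strain") {
    # r(s)^2 is convex in s, so the endpoints are the extremes
    for (s in c(0, L)) {
      p <- pivot + s * dirv - field@center
      if (sum(p^2) > field@dropletRadius^2 * (1 + 1e-12))
        stop("rod exits the droplet at arc length s = ", s, call. = FALSE)
    }
  }
  cPerp <- dragCoefficients(body, viscosity)@cPerp
  integrand <- function(s) {
    px <- pivot[1] + s * dirv[1]
    py <- pivot[2] + s * dirv[2]
    vel <- .velocityRaw(field@pattern, field@strainRate, field@dropletRadius,
                        px - field@center[1], py - field@center[2])
    uth <- -vel$u * sin(theta) + vel$v * cos(theta)
    s * cPerp * (uth - thetaDot * s)
  }
  # the absolute tolerance is floored at the natural torque scale
  # c_perp * U * L^2 so the quadrature stays convergent when the flow and
  # rotation torques cancel (the integrand is then roundoff noise)
  ss <- seq(0, L, length.out = 17)
  vel <- .velocityRaw(field@pattern, field@strainRate, field@dropletRadius,
                      pivot[1] + ss * dirv[1] - field@center[1],
                      pivot[2] + ss * dirv[2] - field@center[2])
  uScale <- max(sqrt(vel$u^2 + vel$v^2)) + abs(thetaDot) * L
  if (uScale == 0) return(0)
  stats::integrate(integrand, 0, L, rel.tol = 1e-11,
                   abs.tol = 1e-13 * cPerp * uScale * L^2,
                   subdivisions = 200L)$value
}

#' Orientation equilibria of a rod in the straining flow
#'
#' The closed-form torque \eqn{-K \sin 2\theta} (with \eqn{K \propto
#' \dot\epsilon}) has exactly two zeros per half-turn. Reported modulo the
#' rod's head--tail symmetry on (0, 180] degrees: for
#' \code{strainRate > 0} the inward-flow heading 90 deg is unstable
#' (a perturbation grows, the torque carries the rod further away) and the
#' outward-flow heading 180 deg is stable (the torque restores it). The
#' angles do not depend on the strain-rate magnitude; stability follows the
#' sign of dT/dtheta at each zero, so a negative strain rate swaps the
#' labels.
#'
#' @param strainRate strain rate (1/s), nonzero.
#' @return data.frame with columns \code{angle_deg} and \code{stability}.
#' @export
equilibria <- function(strainRate) {
  .assertScalar(strainRate, "strainRate")
  if (strainRate == 0)
    stop("strainRate = 0: torque vanishes identically, no isolated equilibria",
         call. = FALSE)
  # dT/dtheta = -2K cos(2 theta), K = (8 pi mu eps / c) L^3 / 3 ~ sign(eps)
  stab <- function(thetaDeg) {
    slope <- -2 * sign(strainRate) * cos(2 * .deg2rad(thetaDeg))
    if (slope > 0) "unstable" else "stable"
  }
  data.frame(angle_deg = c(90, 180),
             stability = c(stab(90), stab(180)),
             stringsAsFactors = FALSE)
}

#' Tabulate the closed-form torque over an angle grid
#'
#' Convenience export used for torque-vs-angle curves; returns a data frame
#' suitable for CSV output.
#'
#' @inheritParams torqueClosedForm
#' @param thetaDeg angle grid in degrees.
#' @return data.frame with columns \code{theta_deg} and \code{torque}.
#' @export
torqueCurve <- function(body, viscosity = 1e-3, strainRate = 1,
                        thetaDeg = seq(0, 180, by = 1)) {
  data.frame(theta_deg = thetaDeg,
             torque = torqueClosedForm(body, viscosity, strainRate,
                                       .deg2rad(thetaDeg)))
}
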