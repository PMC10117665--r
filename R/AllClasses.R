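#' @import methods
NULL

.FLOW_PATTERNS <- c("pure_strain", "one_cell", "two_cell", "four_cell_bounded")
.MOBILITY_CLASSES <- c("intact", "disrupted", "recovering", "indeterminate")

#' In-droplet recirculating flow field
#'
#' Parametric velocity field inside a vibrating sessile droplet. Four patterns
#' are supported: the unbounded planar straining flow (u,v) = (eps*x, -eps*y)
#' and three bounded fields defined by streamfunctions on the droplet disk
#' with one, two or four recirculation cells. The strain rate \code{eps}
#' (1/s) sets the velocity amplitude for all patterns; \code{eps > 0} gives
#' outflow along the x axis (the "source" axis) and inflow along the y axis
#' (the "sink-feeding" axis).
#'
#' @slot pattern character, one of \code{"pure_strain"}, \code{"one_cell"},
#'   \code{"two_cell"}, \code{"four_cell_bounded"}.
#' @slot strainRate numeric, strain-rate amplitude, 1/s.
#' @slot dropletRadius numeric, droplet radius R in metres (ignored for
#'   \code{pure_strain}).
#' @slot center numeric length-2, droplet centre (x, y) in metres.
#'
#' @seealso [flowField()], [velocityAt()], [sampleGrid()]
#' @export
setClass("FlowField",
  representation(pattern = "character", strainRate = "numeric",
                 dropletRadius = "numeric", center = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@pattern) != 1L || !object@pattern %in% .FLOW_PATTERNS)
      msg <- c(msg, sprintf("pattern must be one of: %s",
                            paste(.FLOW_PATTERNS, collapse = ", ")))
    if (length(object@strainRate) != 1L || !is.finite(object@strainRate))
      msg <- c(msg, "strainRate must be a single finite number")
    if (length(object@center) != 2L || any(!is.finite(object@center)))
      msg <- c(msg, "center must be two finite coordinates")
    if (length(object@pattern) == 1L && object@pattern != "pure_strain" &&
        (length(object@dropletRadius) != 1L ||
         !is.finite(object@dropletRadius) || object@dropletRadius <= 0))
      msg <- c(msg, "dropletRadius must be a single positive number for bounded patterns")
    if (is.null(msg)) TRUE else msg
  })

#' Discretised velocity field on a uniform grid
#'
#' A rectangular, uniform grid of velocity samples with an inside-droplet
#' mask. \code{u} and \code{v} are matrices indexed \code{[i, j]} where
#' \code{i} runs over \code{x} and \code{j} over \code{y}.
#'
#' @slot x,y numeric, grid node coordinates (m), strictly increasing, uniform.
#' @slot u,v numeric matrices of velocity components (m/s), dim
#'   \code{c(length(x), length(y))}.
#' @slot mask logical matrix, TRUE for nodes inside the droplet.
#' @slot meta list of provenance metadata (pattern, strain rate, ...).
#'
#' @seealso [sampleGrid()], [classifyPattern()], [velocityGridFromTracks()]
#' @export
setClass("VelocityGrid",
  representation(x = "numeric", y = "numeric", u = "matrix", v = "matrix",
                 mask = "matrix", meta = "list"),
  validity = function(object) {
    msg <- NULL
    dm <- c(length(object@x), length(object@y))
    for (s in c("u", "v", "mask"))
      if (!identical(dim(slot(object, s)), as.integer(dm)))
        msg <- c(msg, sprintf("dim(%s) must be c(length(x), length(y))", s))
    if (length(object@x) > 1 &&
        diff(range(diff(object@x))) > 1e-9 * max(abs(diff(object@x))))
      msg <- c(msg, "x grid must be uniform")
    if (length(object@y) > 1 &&
        diff(range(diff(object@y))) > 1e-9 * max(abs(diff(object@y))))
      msg <- c(msg, "y grid must be uniform")
    if (is.null(msg) && any(object@mask & !(is.finite(object@u) & is.finite(object@v))))
      msg <- c(msg, "u and v must be finite on masked-in nodes")
    if (is.null(msg)) TRUE else msg
  })

#' Slender-body geometry of a rod-like swimmer
#'
#' Geometry of a rod-like body (a larval zebrafish idealised as a straight
#' slender rod): length L and cross-section radius a, both in metres. The
#' slenderness constraint L/a > e keeps the drag-coefficient correction
#' c = 2 ln(L/a) - 1 above 1.
#'
#' @slot lengthL numeric, body length L (m).
#' @slot radiusA numeric, cross-section radius a (m).
#' @seealso [slenderBody()], [dragCoefficients()], [torqueClosedForm()]
#' @export
setClass("SlenderBody",
  representation(lengthL = "numeric", radiusA = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@lengthL) != 1L || !is.finite(object@lengthL) ||
        object@lengthL <= 0)
      msg <- c(msg, "lengthL must be a single positive number")
    if (length(object@radiusA) != 1L || !is.finite(object@radiusA) ||
        object@radiusA <= 0)
      msg <- c(msg, "radiusA must be a single positive number")
    if (is.null(msg) && object@lengthL / object@radiusA <= exp(1))
      msg <- c(msg, "lengthL/radiusA must exceed e (slender-body validity)")
    if (is.null(msg)) TRUE else msg
  })

#' Slender-body drag coefficients
#'
#' The dimensionless correction c = 2 ln(L/a) - 1 and the per-unit-length
#' drag coefficients parallel (4*pi*mu/c) and perpendicular (8*pi*mu/c) to
#' the body axis; the perpendicular coefficient is exactly twice the
#' parallel one.
#'
#' @slot cCorrection numeric, dimensionless correction c.
#' @slot cParallel numeric, parallel drag per unit length (Pa s).
#' @slot cPerp numeric, perpendicular drag per unit length (Pa s).
#' @seealso [dragCoefficients()]
#' @export
setClass("DragCoefficients",
  representation(cCorrection = "numeric", cParallel = "numeric",
                 cPerp = "numeric"),
  validity = function(object) {
    msg <- NULL
    vals <- c(object@cCorrection, object@cParallel, object@cPerp)
    if (length(vals) != 3L || any(!is.finite(vals)) || any(vals <= 0))
      msg <- c(msg, "all coefficients must be single positive numbers")
    if (is.null(msg) &&
        abs(object@cPerp - 2 * object@cParallel) > 1e-12 * object@cPerp)
      msg <- c(msg, "cPerp must equal 2 * cParallel")
    if (is.null(msg)) TRUE else msg
  })

#' Body-orientation time series of one fish
#'
#' Heading angle of a single fish over time, degrees in [0, 360) measured
#' counterclockwise from the outward-flow (source) x axis. \code{meta}
#' records the parameters the trajectory was simulated or measured with.
#'
#' @slot times numeric, sample times (s), strictly increasing.
#' @slot anglesDeg numeric, heading per sample, degrees in [0, 360).
#' @slot meta list of parameters (activity, noise, strain rate, seed, ...).
#' @seealso [simulateSwimmer()], [mobilityReport()]
#' @export
setClass("OrientationTrajectory",
  representation(times = "numeric", anglesDeg = "numeric", meta = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@anglesDeg))
      msg <- c(msg, "times and anglesDeg must have the same length")
    if (length(object@times) > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(!is.finite(object@anglesDeg)) ||
        any(object@anglesDeg < 0 | object@anglesDeg >= 360))
      msg <- c(msg, "anglesDeg must be finite and wrapped to [0, 360)")
    if (is.null(msg)) TRUE else msg
  })

#' Image stack with acquisition metadata
#'
#' A T-frame grayscale image stack. Frames are stored as an array with
#' dimensions (height, width, frames); pixel (row, col) = (1, 1) is the
#' top-left corner, pixel centres sit at integer pixel coordinates with
#' origin (0, 0) at the top-left pixel centre, x rightward and y downward.
#'
#' @slot frames numeric array, dim (H, W, T), nonnegative intensities.
#' @slot frameRate numeric, frames per second.
#' @slot pxScale numeric, metres per pixel.
#' @seealso [renderScene()], [detectBlobs()], [readFrameStack()]
#' @export
setClass("FrameStack",
  representation(frames = "array", frameRate = "numeric", pxScale = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@frames)
    if (length(d) != 3L || d[3] < 2L)
      msg <- c(msg, "frames must be an (H, W, T) array with T >= 2")
    if (any(!is.finite(object@frames)) || any(object@frames < 0))
      msg <- c(msg, "intensities must be finite and >= 0")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a single positive number")
    if (length(object@pxScale) != 1L || object@pxScale <= 0)
      msg <- c(msg, "pxScale must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Per-fish mobility report
#'
#' Circular summary of one fish's heading series together with the folded
#' deviations from the source (inward-flow, 90/270 degrees) and sink
#' (outward-flow, 0/180 degrees) axes and the mobility class label.
#'
#' @slot circMeanDeg numeric, circular mean heading (deg), NA if undefined.
#' @slot resultantLength numeric in [0, 1], mean resultant length.
#' @slot sourceDeviationDeg numeric in [0, 90].
#' @slot sinkDeviationDeg numeric in [0, 90].
#' @slot classLabel character, one of intact / disrupted / recovering /
#'   indeterminate.
#' @slot meta list (fish id, ground-truth type, thresholds used, ...).
#' @seealso [mobilityReport()], [classifyMobility()]
#' @export
setClass("MobilityReport",
  representation(circMeanDeg = "numeric", resultantLength = "numeric",
                 sourceDeviationDeg = "numeric", sinkDeviationDeg = "numeric",
                 classLabel = "character", meta = "list"),
  validity = function(object) {
    msg <- NULL
    if (!is.na(object@resultantLength) &&
        (object@resultantLength < 0 || object@resultantLength > 1))
      msg <- c(msg, "resultantLength must lie in [0, 1]")
    for (s in c("sourceDeviationDeg", "sinkDeviationDeg")) {
      v <- slot(object, s)
      if (!is.na(v) && (v < 0 || v > 90))
        msg <- c(msg, sprintf("%s must lie in [0, 90]", s))
    }
    if (!object@classLabel %in% .MOBILITY_CLASSES)
      msg <- c(msg, "classLabel must be a recognised mobility class")
    if (is.null(msg)) TRUE else msg
  })
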