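#' @rdname FlowField-class
#' @param object,x an object
#' @export
setGeneric("flowPattern", function(object) standardGeneric("flowPattern"))
#' @rdname FlowField-class
#' @export
setGeneric("strainRate", function(object) standardGeneric("strainRate"))
#' @rdname FlowField-class
#' @export
setGeneric("dropletRadius", function(object) standardGeneric("dropletRadius"))

#' @rdname SlenderBody-class
#' @param object an object
#' @export
setGeneric("bodyLength", function(object) standardGeneric("bodyLength"))
#' @rdname SlenderBody-class
#' @export
setGeneric("bodyRadius", function(object) standardGeneric("bodyRadius"))

#' @rdname OrientationTrajectory-class
#' @param object an object
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname OrientationTrajectory-class
#' @export
setGeneric("headingDeg", function(object) standardGeneric("headingDeg"))

#' @rdname MobilityReport-class
#' @param object an object
#' @export
setGeneric("mobilityClass", function(object) standardGeneric("mobilityClass"))

setMethod("flowPattern", "FlowField", function(object) object@pattern)
setMethod("strainRate", "FlowField", function(object) object@strainRate)
setMethod("dropletRadius", "FlowField", function(object) object@dropletRadius)

setMethod("bodyLength", "SlenderBody", function(object) object@lengthL)
setMethod("bodyRadius", "SlenderBody", function(object) object@radiusA)

setMethod("sampleTimes", "OrientationTrajectory", function(object) object@times)
setMethod("headingDeg", "OrientationTrajectory", function(object) object@anglesDeg)

setMethod("mobilityClass", "MobilityReport", function(object) object@classLabel)

setMethod("show", "FlowField", function(object) {
  cat("FlowField:", object@pattern, "\n")
  cat("  strain rate:", object@strainRate, "1/s\n")
  if (object@pattern != "pure_strain")
    cat("  droplet radius:", object@dropletRadius, "m, center: (",
        object@center[1], ",", object@center[2], ") m\n")
  invisible(NULL)
})

setMethod("show", "VelocityGrid", function(object) {
  cat(sprintf("VelocityGrid: %d x %d nodes, %d inside mask\n",
              length(object@x), length(object@y), sum(object@mask)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "SlenderBody", function(object) {
  cat(sprintf("SlenderBody: L = %g m, a = %g m (L/a = %.3g)\n",
              object@lengthL, object@radiusA, object@lengthL / object@radiusA))
  invisible(NULL)
})

setMethod("show", "DragCoefficients", function(object) {
  cat(sprintf("DragCoefficients: c = %.6g, c_par = %.6g, c_perp = %.6g Pa s\n",
              object@cCorrection, object@cParallel, object@cPerp))
  invisible(NULL)
})

setMethod("show", "OrientationTrajectory", function(object) {
  n <- length(object@times)
  cat(sprintf("OrientationTrajectory: %d samples over %.3g s\n",
              n, if (n) diff(range(object@times)) else 0))
  if (n)
    cat(sprintf("  heading: start %.1f deg, end %.1f deg\n",
                object@anglesDeg[1], object@anglesDeg[n]))
  invisible(NULL)
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d frames of %d x %d px, %g fps, %g m/px\n",
              d[3], d[1], d[2], object@frameRate, object@pxScale))
  invisible(NULL)
})

setMethod("show", "MobilityReport", function(object) {
  cat("MobilityReport:", object@classLabel, "\n")
  cat(sprintf("  circular mean %.1f deg (R = %.3f)\n",
              object@circMeanDeg, object@resultantLength))
  cat(sprintf("  deviation from source %.1f deg, from sink %.1f deg\n",
              object@sourceDeviationDeg, object@sinkDeviationDeg))
  invisible(NULL)
})
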