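#' Mean squared displacement of a centroid track
#'
#' \deqn{\mathrm{MSD}(\tau) = \langle [r(t+\tau) - r(t)]^2 \rangle,} the
#' average over all overlapping time origins t of the squared displacement
#' at lag tau. The track must be uniformly sampled and each lag a multiple
#' of the sampling interval; lags at or beyond the track duration are
#' dropped with a warning.
#'
#' @param track data.frame with columns \code{time_s}, \code{x_m},
#'   \code{y_m} for a single track.
#' @param lags lag times (s); default all multiples of dt up to half the
#'   track duration.
#' @return data.frame with columns \code{lag_s} and \code{msd} (m^2);
#'   MSD(0) = 0 is included when lag 0 is requested.
#' @export
msdCurve <- function(track, lags = NULL) {
  stopifnot(all(c("time_s", "x_m", "y_m") %in% names(track)))
  n <- nrow(track)
  if (n < 2) stop("track needs at least 2 samples")
  o <- order(track$time_s)
  t <- track$time_s[o]; x <- track$x_m[o]; y <- track$y_m[o]
  dts <- diff(t)
  if (diff(range(dts)) > 1e-9 * mean(dts))
    stop("track must be uniformly sampled")
  dt <- mean(dts)
  if (is.null(lags)) lags <- dt * seq_len(max(1L, floor((n - 1) / 2)))
  ks <- round(lags / dt)
  if (any(abs(ks * dt - lags) > 1e-9 * dt))
    stop("each lag must be a multiple of the sampling interval")
  drop <- ks >= n
  if (any(drop)) {
    warning(sum(drop), " lag(s) at or beyond the track duration dropped")
    ks <- ks[!drop]; lags <- lags[!drop]
  }
  msd <- vapply(ks, function(k) {
    if (k == 0) return(0)
    i <- seq_len(n - k)
    mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  }, numeric(1))
  data.frame(lag_s = lags, msd = msd)
}

#' Circular mean and resultant length of heading angles
#'
#' The mean of the unit heading vectors: its direction is the circular
#' mean (wrapped to [0, 360)) and its norm the resultant length R in
#' [0, 1]. When the vectors cancel (R numerically zero, e.g. angles split
#' evenly between 0 and 180 degrees) the mean is undefined and returned as
#' NA with \code{undefined = TRUE}.
#'
#' @param anglesDeg heading angles in degrees.
#' @return list with \code{meanDeg}, \code{resultantLength},
#'   \code{undefined}.
#' @export
circularSummary <- function(anglesDeg) {
  if (!length(anglesDeg)) stop("need at least one angle")
  th <- .deg2rad(anglesDeg)
  cbar <- mean(cos(th)); sbar <- mean(sin(th))
  R <- sqrt(cbar^2 + sbar^2)
  if (R < 1e-12)
    return(list(meanDeg = NA_real_, resultantLength = 0, undefined = TRUE))
  list(meanDeg = .wrap360(.rad2deg(atan2(sbar, cbar))),
       resultantLength = min(R, 1), undefined = FALSE)
}

#' Folded deviation from the source (inward-flow) axis
#'
#' Minimum angular distance to the source-facing directions 90 and 270
#' degrees, in [0, 90]. Fish holding either heading are both source-aligned
#' (the rod is head--tail symmetric mechanically; behaviourally both
#' upstream headings occur).
#'
#' @param angleDeg heading in degrees; vectorised.
#' @return deviation in degrees, [0, 90].
#' @seealso [sinkDeviation()]; the two deviations sum to 90 for any angle.
#' @export
sourceDeviation <- function(angleDeg) {
  pmin(.circDistDeg(angleDeg, 90), .circDistDeg(angleDeg, 270))
}

#' Folded deviation from the sink (outward-flow) axis
#'
#' Minimum angular distance to the directions 0 and 180 degrees, in
#' [0, 90].
#'
#' @inheritParams sourceDeviation
#' @return deviation in degrees, [0, 90].
#' @export
sinkDeviation <- function(angleDeg) {
  pmin(.circDistDeg(angleDeg, 0), .circDistDeg(angleDeg, 180))
}

#' Chance probability that a cohort aligns within one angular window
#'
#' For n fish with independent uniform headings and a fixed partition of
#' the circle into 360/w windows of width w, the union bound on all n fish
#' falling into the same window is
#' \deqn{p = (w/360)^n \cdot (360/w),}
#' capped at 1. For the cohort of 5 fish in a 30-degree window this gives
#' (1/12)^5 * 12 = 12^-4 = 4.8225e-5.
#'
#' @param nFish cohort size, at least 1.
#' @param windowDeg window width in degrees; must divide 360 (the
#'   combinatorial factor counts the windows of a partition).
#' @return the alignment probability.
#' @export
chanceAlignmentPvalue <- function(nFish, windowDeg = 30) {
  if (nFish < 1 || nFish != round(nFish)) stop("nFish must be a positive integer")
  .assertScalar(windowDeg, "windowDeg", positive = TRUE)
  if (abs(360 / windowDeg - round(360 / windowDeg)) > 1e-9)
    stop("windowDeg must divide 360", call. = FALSE)
  nWin <- round(360 / windowDeg)
  min(1, (windowDeg / 360)^nFish * nWin)
}

.DEFAULT_THRESHOLDS <- list(
  intact_dev = 10, intact_R = 0.9,
  disrupted_dev = 20, disrupted_R = 0.9,
  recovering_dev = 40, recovering_R = 0.5)

#' Classify a fish's mobility from its circular summary
#'
#' Decision rule over the circular-mean heading and resultant length,
#' with thresholds taken from the observed angle windows: intact fish hold
#' the source axis tightly (folded source deviation at most 10 degrees,
#' matching the 80--100 degree band), disrupted fish are pinned near the
#' sink axis (folded sink deviation at most 20 degrees, covering the
#' -20..20 and 180..220 degree ranges), recovering fish sit within 40
#' degrees of the source with looser clustering. Everything else — or an
#' undefined mean — is indeterminate. The thresholds are configurable.
#'
#' @param circMeanDeg circular mean heading (degrees), NA if undefined.
#' @param resultantLength mean resultant length in [0, 1].
#' @param thresholds named list overriding any of intact_dev, intact_R,
#'   disrupted_dev, disrupted_R, recovering_dev, recovering_R.
#' @return one of "intact", "disrupted", "recovering", "indeterminate".
#' @export
classifyMobility <- function(circMeanDeg, resultantLength,
                             thresholds = list()) {
  th <- utils::modifyList(.DEFAULT_THRESHOLDS, thresholds)
  if (is.na(circMeanDeg)) return("indeterminate")
  sdev <- sourceDeviation(circMeanDeg)
  kdev <- sinkDeviation(circMeanDeg)
  if (sdev <= th$intact_dev && resultantLength >= th$intact_R) return("intact")
  if (kdev <= th$disrupted_dev && resultantLength >= th$disrupted_R)
    return("disrupted")
  if (sdev <= th$recovering_dev && resultantLength >= th$recovering_R)
    return("recovering")
  "indeterminate"
}

#' Per-fish mobility report
#'
#' Computes the circular summary of a heading series, the folded source and
#' sink deviations of the mean heading, and the mobility class.
#'
#' @param traj an [OrientationTrajectory-class], or a numeric vector of
#'   heading angles in degrees.
#' @param thresholds passed to [classifyMobility()].
#' @param meta list merged into the report metadata (fish id, truth, ...).
#' @return a [MobilityReport-class].
#' @export
mobilityReport <- function(traj, thresholds = list(), meta = list()) {
  angles <- if (is(traj, "OrientationTrajectory")) traj@anglesDeg
            else .wrap360(as.numeric(traj))
  cs <- circularSummary(angles)
  label <- classifyMobility(cs$meanDeg, cs$resultantLength, thresholds)
  new("MobilityReport",
      circMeanDeg = cs$meanDeg,
      resultantLength = cs$resultantLength,
      sourceDeviationDeg = if (cs$undefined) NA_real_
                           else sourceDeviation(cs$meanDeg),
      sinkDeviationDeg = if (cs$undefined) NA_real_
                         else sinkDeviation(cs$meanDeg),
      classLabel = label,
      meta = c(meta, list(n_samples = length(angles),
                          thresholds = utils::modifyList(.DEFAULT_THRESHOLDS,
                                                         thresholds))))
}

#' Recovery trend of the folded heading over time bins
#'
#' Tracks how a recovering fish's heading climbs from the sink axis
#' (folded angle 0) to the source axis (folded angle 90) across an
#' observation window. The folded angle of each time bin is the sink
#' deviation of its circular-mean heading. Reported: first and last bin
#' values and the linearly interpolated time at which the folded angle
#' first crosses the 45-degree midpoint. A series that decreases anywhere
#' along the way is flagged non-monotone; the crossing time still refers
#' to the first crossing.
#'
#' @param binTimes bin centre times (s), increasing, at least 3 bins.
#' @param binMeanDeg circular-mean heading per bin (degrees).
#' @return list with \code{initialDeg}, \code{finalDeg},
#'   \code{timeToHalf_s} (NA if the midpoint is never crossed),
#'   \code{monotone}, and \code{foldedDeg} (per-bin folded angles).
#' @export
recoveryTrend <- function(binTimes, binMeanDeg) {
  if (length(binTimes) < 3) stop("need at least 3 time bins")
  if (length(binTimes) != length(binMeanDeg))
    stop("binTimes and binMeanDeg must have the same length")
  if (any(diff(binTimes) <= 0)) stop("binTimes must be increasing")
  folded <- sinkDeviation(.wrap360(binMeanDeg))
  n <- length(folded)
  cross <- which(folded[-1] >= 45 & folded[-n] < 45)
  timeToHalf <- if (folded[1] >= 45) binTimes[1]
  else if (!length(cross)) NA_real_
  else {
    i <- cross[1]
    binTimes[i] + (45 - folded[i]) / (folded[i + 1] - folded[i]) *
      (binTimes[i + 1] - binTimes[i])
  }
  list(initialDeg = folded[1], finalDeg = folded[n],
       timeToHalf_s = timeToHalf,
       monotone = all(diff(folded) >= -1e-9),
       foldedDeg = folded)
}

#' Cohort summary table
#'
#' One row per fish: id, ground-truth type (when known), flow pattern,
#' circular-mean heading, resultant length, folded deviations and assigned
#' class, mirroring a cohort results table. Also computes the cohort
#' alignment probability: if the minimal enclosing arc of the fish's mean
#' headings fits within one window of width \code{windowDeg}, the
#' chance-alignment p-value for the cohort size is attached (NA
#' otherwise).
#'
#' @param reports list of [MobilityReport-class] objects.
#' @param windowDeg alignment window width (degrees), default 30.
#' @return list with \code{table} (data.frame) and \code{alignmentP}.
#' @export
cohortTable <- function(reports, windowDeg = 30) {
  stopifnot(length(reports) >= 1)
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(
      fish_id = if (!is.null(r@meta$fish_id)) r@meta$fish_id else i,
      type = if (!is.null(r@meta$type)) r@meta$type else NA_character_,
      pattern = if (!is.null(r@meta$pattern)) r@meta$pattern
                else NA_character_,
      mean_angle_deg = r@circMeanDeg,
      resultant_length = r@resultantLength,
      source_deviation_deg = r@sourceDeviationDeg,
      sink_deviation_deg = r@sinkDeviationDeg,
      class = r@classLabel,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  means <- tab$mean_angle_deg
  alignmentP <- NA_real_
  if (!any(is.na(means))) {
    # aligned if the minimal enclosing arc of the means fits in one window
    a <- sort(.wrap360(means))
    gaps <- diff(c(a, a[1] + 360))
    if (360 - max(gaps) <= windowDeg)
      alignmentP <- chanceAlignmentPvalue(length(means), windowDeg)
  }
  list(table = tab, alignmentP = alignmentP)
}
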