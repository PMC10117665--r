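#' Construct a frame stack
#'
#' @param frames numeric array (H, W, T) of nonnegative intensities.
#' @param frameRate frames per second (20 fps for fish videos, 30 fps for
#'   tracer-particle recordings by default elsewhere).
#' @param pxScale metres per pixel.
#' @return a [FrameStack-class].
#' @export
frameStack <- function(frames, frameRate = 20, pxScale = 2e-5) {
  new("FrameStack", frames = frames, frameRate = as.numeric(frameRate),
      pxScale = as.numeric(pxScale))
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax < 2L) return(lab)
  parent <- seq_len(nmax)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right diagonal
  for (k in which(a > 0 & b > 0 & a != b)) unite(a[k], b[k])
  a <- lab[-1, -nc]; b <- lab[-nr, -1]    # up-right diagonal
  for (k in which(a > 0 & b > 0 & a != b)) unite(a[k], b[k])
  roots <- vapply(seq_len(nmax), findRoot, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0
  lab[pos] <- relab[lab[pos]]
  lab
}

#' Detect bright blobs in a single frame
#'
#' Thresholds the frame at a fraction of its maximum intensity (making
#' detection invariant to overall intensity scale), labels 8-connected
#' components, and keeps components of at least \code{minArea} pixels.
#' Centroids are intensity-weighted; orientation comes from the second
#' central image moments (principal axis), reported modulo 180 degrees in
#' the physical convention (counterclockwise from +x with y pointing up).
#'
#' @param frame numeric matrix (H, W), rows are image rows (y down).
#' @param threshold fraction of the frame maximum, in (0, 1).
#' @param minArea minimum component area in pixels.
#' @return data.frame with columns x_px, y_px (pixel-centre coordinates,
#'   origin at the top-left pixel centre), area_px, orientation_deg,
#'   intensity (summed). Zero rows when nothing is detected.
#' @export
detectBlobs <- function(frame, threshold = 0.5, minArea = 4) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = integer(0), orientation_deg = numeric(0),
                      intensity = numeric(0))
  mx <- max(frame)
  if (mx <= 0) return(empty)
  mask <- frame >= threshold * mx
  if (!any(mask)) return(empty)
  lab <- .label8(mask)
  nlab <- max(lab)
  rows <- row(frame) - 1  # y, 0-based pixel centres
  cols <- col(frame) - 1  # x
  out <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    sel <- lab == l
    area <- sum(sel)
    if (area < minArea) next
    w <- frame[sel]
    sw <- sum(w)
    xc <- sum(w * cols[sel]) / sw
    yc <- sum(w * rows[sel]) / sw
    mu20 <- sum(w * (cols[sel] - xc)^2) / sw
    mu02 <- sum(w * (rows[sel] - yc)^2) / sw
    mu11 <- sum(w * (cols[sel] - xc) * (rows[sel] - yc)) / sw
    angImg <- 0.5 * atan2(2 * mu11, mu20 - mu02)
    out[[l]] <- data.frame(x_px = xc, y_px = yc, area_px = area,
                           orientation_deg = (-.rad2deg(angImg)) %% 180,
                           intensity = sw)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Detect blobs in every frame of a stack
#'
#' @param stack a [FrameStack-class].
#' @inheritParams detectBlobs
#' @return data.frame as [detectBlobs()] with additional columns
#'   \code{frame} (1-based) and \code{time_s}.
#' @export
detectStack <- function(stack, threshold = 0.5, minArea = 4) {
  stopifnot(is(stack, "FrameStack"))
  nT <- dim(stack@frames)[3]
  res <- vector("list", nT)
  for (f in seq_len(nT)) {
    d <- detectBlobs(stack@frames[, , f], threshold, minArea)
    if (nrow(d)) {
      d$frame <- f
      d$time_s <- (f - 1) / stack@frameRate
    } else {
      d$frame <- integer(0); d$time_s <- numeric(0)
    }
    res[[f]] <- d
  }
  do.call(rbind, res)
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame assignment by optimal bipartite matching on Euclidean
#' displacement (Hungarian method via \code{clue::solve_LSAP}); candidate
#' pairs farther than \code{maxDispPx} are excluded, unmatched detections
#' start new tracks, and a detection missing for one frame ends its track
#' (no gap closing). Detections within a frame are sorted by position
#' before matching, so the result does not depend on their input order.
#'
#' Pixel positions are converted to physical coordinates centred on the
#' image with y flipped to point up, so track angles follow the flow-model
#' convention.
#'
#' @param detections data.frame from [detectStack()].
#' @param stack the [FrameStack-class] the detections came from (supplies
#'   image size, frame rate and pixel scale).
#' @param maxDispPx maximum per-frame displacement (pixels).
#' @return data.frame with columns track_id, frame, time_s, x_px, y_px,
#'   x_m, y_m, orientation_deg.
#' @export
linkTracks <- function(detections, stack, maxDispPx = 5) {
  stopifnot(is(stack, "FrameStack"))
  d <- dim(stack@frames)
  H <- d[1]; W <- d[2]
  cols <- c("track_id", "frame", "time_s", "x_px", "y_px", "x_m", "y_m",
            "orientation_deg")
  if (is.null(detections) || !nrow(detections))
    return(stats::setNames(as.data.frame(replicate(length(cols), numeric(0),
                                                   simplify = FALSE)), cols))
  BIG <- 1e9
  detections <- detections[order(detections$frame, detections$x_px,
                                 detections$y_px), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  nextId <- 1L
  rows <- list()
  active <- NULL  # data.frame: id, x, y, frame
  for (f in frames) {
    df <- detections[detections$frame == f, , drop = FALSE]
    ids <- integer(nrow(df))
    carry <- if (!is.null(active)) active[active$frame == f - 1, , drop = FALSE]
             else NULL
    if (!is.null(carry) && nrow(carry) && nrow(df)) {
      cost <- outer(seq_len(nrow(carry)), seq_len(nrow(df)),
                    function(i, j) sqrt((carry$x[i] - df$x_px[j])^2 +
                                        (carry$y[i] - df$y_px[j])^2))
      cost[cost > maxDispPx] <- BIG
      if (nrow(cost) <= ncol(cost)) {
        ass <- as.integer(clue::solve_LSAP(cost))
        for (i in seq_along(ass)) {
          j <- ass[i]
          if (cost[i, j] < BIG) ids[j] <- carry$id[i]
        }
      } else {
        ass <- as.integer(clue::solve_LSAP(t(cost)))
        for (j in seq_along(ass)) {
          i <- ass[j]
          if (cost[i, j] < BIG) ids[j] <- carry$id[i]
        }
      }
    }
    for (j in seq_len(nrow(df))) {
      if (ids[j] == 0L) {
        ids[j] <- nextId
        nextId <- nextId + 1L
      }
    }
    if (nrow(df)) {
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = ids, frame = df$frame, time_s = df$time_s,
        x_px = df$x_px, y_px = df$y_px,
        x_m = (df$x_px - (W - 1) / 2) * stack@pxScale,
        y_m = ((H - 1) / 2 - df$y_px) * stack@pxScale,
        orientation_deg = df$orientation_deg)
      active <- data.frame(id = ids, x = df$x_px, y = df$y_px, frame = f)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

#' Reconstruct a velocity grid from tracked tracer particles
#'
#' Particle-tracking velocimetry: every consecutive-frame displacement of
#' every track yields a velocity sample at the step midpoint; samples are
#' binned to a uniform grid and averaged per cell, cells without samples
#' are masked out.
#'
#' @param tracks data.frame from [linkTracks()] (columns track_id, frame,
#'   time_s, x_m, y_m).
#' @param nPerAxis grid nodes per axis.
#' @param xlim,ylim grid extent (m); defaults to the symmetric bounding box
#'   of the samples.
#' @return a [VelocityGrid-class].
#' @export
velocityGridFromTracks <- function(tracks, nPerAxis = 48, xlim = NULL,
                                   ylim = NULL) {
  samp <- list(x = numeric(0), y = numeric(0), u = numeric(0), v = numeric(0))
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) next
    step <- which(diff(tr$frame) == 1)
    if (!length(step)) next
    dt <- tr$time_s[step + 1] - tr$time_s[step]
    samp$x <- c(samp$x, (tr$x_m[step] + tr$x_m[step + 1]) / 2)
    samp$y <- c(samp$y, (tr$y_m[step] + tr$y_m[step + 1]) / 2)
    samp$u <- c(samp$u, (tr$x_m[step + 1] - tr$x_m[step]) / dt)
    samp$v <- c(samp$v, (tr$y_m[step + 1] - tr$y_m[step]) / dt)
  }
  if (!length(samp$x)) stop("no displacement samples in the tracks")
  if (is.null(xlim)) {
    half <- max(abs(samp$x)) * 1.01
    xlim <- c(-half, half)
  }
  if (is.null(ylim)) {
    half <- max(abs(samp$y)) * 1.01
    ylim <- c(-half, half)
  }
  x <- seq(xlim[1], xlim[2], length.out = nPerAxis)
  y <- seq(ylim[1], ylim[2], length.out = nPerAxis)
  ix <- pmin(pmax(round((samp$x - x[1]) / (x[2] - x[1])) + 1, 1), nPerAxis)
  iy <- pmin(pmax(round((samp$y - y[1]) / (y[2] - y[1])) + 1, 1), nPerAxis)
  u <- matrix(0, nPerAxis, nPerAxis)
  v <- matrix(0, nPerAxis, nPerAxis)
  n <- matrix(0, nPerAxis, nPerAxis)
  for (k in seq_along(ix)) {
    u[ix[k], iy[k]] <- u[ix[k], iy[k]] + samp$u[k]
    v[ix[k], iy[k]] <- v[ix[k], iy[k]] + samp$v[k]
    n[ix[k], iy[k]] <- n[ix[k], iy[k]] + 1
  }
  mask <- n > 0
  u[mask] <- u[mask] / n[mask]
  v[mask] <- v[mask] / n[mask]
  u[!mask] <- NA_real_; v[!mask] <- NA_real_
  new("VelocityGrid", x = x, y = y, u = u, v = v, mask = mask,
      meta = list(source = "ptv", n_samples = length(ix)))
}

#' Write / read a frame stack as multi-page TIFF plus JSON metadata
#'
#' Intensities are scaled to [0, 1] on write (the maximum is stored in the
#' sidecar and restored on read).
#'
#' @param stack a [FrameStack-class].
#' @param path TIFF file path; metadata go to \code{<path>.json}.
#' @return \code{writeFrameStack} returns \code{path} invisibly;
#'   \code{readFrameStack} a [FrameStack-class].
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  mx <- max(stack@frames, 1e-12)
  pages <- lapply(seq_len(dim(stack@frames)[3]),
                  function(f) stack@frames[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(frame_rate = stack@frameRate,
                            px_scale = stack@pxScale, intensity_max = mx),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list(frame_rate = 20, px_scale = 2e-5, intensity_max = 1)
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * meta$intensity_max
  frameStack(arr, frameRate = meta$frame_rate, pxScale = meta$px_scale)
}
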