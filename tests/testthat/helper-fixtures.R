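# Shared fixture builders; everything is generated in code at test time.

# render an isotropic Gaussian spot into an (H, W) frame, 0-based centre
renderSpot <- function(H, W, x0, y0, sigma = 1.5, amp = 1) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  amp * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * sigma^2))
}

# anisotropic Gaussian at a physical-convention angle (deg, y up)
renderEllipse <- function(H, W, x0, y0, angleDeg, sigLong = 6,
                          sigShort = 1.5) {
  th <- angleDeg * pi / 180
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  dx <- xs - x0
  dy <- -(ys - y0)  # flip to y-up
  a <- dx * cos(th) + dy * sin(th)
  b <- -dx * sin(th) + dy * cos(th)
  exp(-a^2 / (2 * sigLong^2) - b^2 / (2 * sigShort^2))
}

# fraction of ground-truth positions matched by a detection within tolPx
truthRecovery <- function(truth, detections, tolPx = 0.5) {
  ok <- 0L; tot <- 0L
  for (f in unique(truth$frame)) {
    tr <- truth[truth$frame == f, , drop = FALSE]
    dd <- detections[detections$frame == f, , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      tot <- tot + 1L
      if (nrow(dd)) {
        d <- sqrt((dd$x_px - tr$x_px[i])^2 + (dd$y_px - tr$y_px[i])^2)
        if (min(d) <= tolPx) ok <- ok + 1L
      }
    }
  }
  ok / tot
}

# map each linked track to the ground-truth particle ids it follows
trackTruthIds <- function(tracks, truth, tolPx = 0.5) {
  lapply(split(tracks, tracks$track_id), function(tr) {
    ids <- integer(0)
    for (k in seq_len(nrow(tr))) {
      tt <- truth[truth$frame == tr$frame[k], , drop = FALSE]
      d <- sqrt((tt$x_px - tr$x_px[k])^2 + (tt$y_px - tr$y_px[k])^2)
      if (length(d) && min(d) <= tolPx) ids <- c(ids, tt$id[which.min(d)])
    }
    ids
  })
}

# default slender fish used across tests: 10 mm rod, L/a = 20
testBody <- function() slenderBody(1e-2, 5e-4)
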