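# Run-tumble statistics from 3D tracks: spline smoothing, motility
# filtering, reorientation detection and the summary distributions.

#' Smooth a 3D track with piecewise cubic splines
#'
#' Each coordinate is fitted with cubic smoothing splines against time at
#' two smoothing levels chosen from the track's noise scales.  Velocity and
#' speed use a lighter spline whose cutoff keeps localization noise out of
#' the first derivative; the swimming direction and its change rate
#' d(theta)/dt use a stronger spline that additionally suppresses
#' translational Brownian motion, because the direction derivative amplifies
#' both noise sources much more strongly.  Both cutoffs follow from the
#' white-noise/diffusion spectra (see the internal rule `.splineByNoise`);
#' with a zero noise scale the generalized cross-validation choice of
#' [stats::smooth.spline()] is used for everything.
#'
#' @param track data.frame with `t`, `x`, `y`, `z` (s, um) and optionally
#'   `trackId`
#' @param sigmaXY,sigmaZ localization noise (um)
#' @param transDiff translational diffusivity entering the smoothing rule
#'   (um^2/s; ~0.2 for a 1-2 um bacterium)
#' @return a [SmoothedTrack-class], or `NULL` (with a warning) for tracks
#'   shorter than 10 samples
#' @export
smoothTrack <- function(track, sigmaXY = 0.5, sigmaZ = 1.0,
                        transDiff = 0.2) {
  if (nrow(track) < 10) {
    warning("track too short to smooth (", nrow(track), " < 10 samples)")
    return(NULL)
  }
  t <- track$t
  pos <- vel <- matrix(0, nrow(track), 3)
  sig <- c(sigmaXY, sigmaXY, sigmaZ)
  # pilot fit for the speed scale entering the cutoff rule
  vGuess <- NULL
  if (any(sig > 0)) {
    vg <- numeric(3)
    for (k in 1:3) {
      f0 <- stats::smooth.spline(t, track[[c("x", "y", "z")[k]]],
                                 df = max(4, diff(range(t)) * 2))
      vg[k] <- median(abs(predict(f0, t, deriv = 1)$y))
    }
    vGuess <- max(5, sqrt(sum(vg^2)))
  }
  dvel <- matrix(0, nrow(track), 3)
  for (k in 1:3) {
    yk <- track[[c("x", "y", "z")[k]]]
    fit <- .splineByNoise(t, yk, sig[k], vGuess, transDiff = 0)
    pos[, k] <- predict(fit, t)$y
    vel[, k] <- predict(fit, t, deriv = 1)$y
    dirFit <- .splineByNoise(t, yk, sig[k], vGuess, transDiff)
    dvel[, k] <- predict(dirFit, t, deriv = 1)$y
  }
  speed <- sqrt(rowSums(vel^2))
  dir <- dvel / pmax(sqrt(rowSums(dvel^2)), 1e-12)
  # angular speed from the turning of the unit direction between samples
  n <- nrow(dir)
  dth <- acos(pmin(1, pmax(-1, rowSums(dir[-n, , drop = FALSE] *
                                       dir[-1, , drop = FALSE]))))
  dt <- diff(t)
  angMid <- dth / dt * 180 / pi
  ang <- c(angMid[1], (angMid[-1] + angMid[-(n - 1)]) / 2, angMid[n - 1])
  new("SmoothedTrack", t = t, pos = pos, vel = vel, speed = speed, dir = dir,
      angSpeed = ang,
      trackId = as.integer(track$trackId[1] %||% 1L))
}

# Smoothing spline with cutoff frequency set by the track's noise scales.
# Two fluctuation sources corrupt the direction derivative: localization
# noise (white, sd sigma) and translational Brownian motion (diffusivity D).
# Low-passed at cutoff fc they leave an angular-speed noise of variance
#   (2 pi)^4 2 sigma^2 fc^5 / (5 fN v^2)  +  (2 pi)^2 8 D fc^3 / (3 v^2);
# fc is chosen so the combined rms stays at a third of the 5 deg/s
# reorientation threshold, keeping spurious peaks rare while leaving
# genuine turns (which sweep tens of deg/s even after smoothing) intact.
.splineByNoise <- function(t, y, sigma, vGuess = NULL, transDiff = 0.2,
                           angNoiseTarget = 5 / 3) {
  if (sigma <= 0) return(stats::smooth.spline(t, y))
  T <- diff(range(t))
  fN <- 0.5 * (length(t) - 1) / T
  v <- if (is.null(vGuess)) 30 else vGuess
  target2 <- (angNoiseTarget * pi / 180)^2
  noiseVar <- function(fc)
    (2 * pi)^4 * 2 * sigma^2 * fc^5 / (5 * fN * v^2) +
    (2 * pi)^2 * 8 * transDiff * fc^3 / (3 * v^2)
  if (noiseVar(fN) < target2) return(stats::smooth.spline(t, y))
  fc <- stats::uniroot(function(f) noiseVar(f) - target2,
                       lower = 1e-6, upper = fN)$root
  fc <- min(max(fc, 0.2), fN / 2)
  df <- min(max(4, round(2 * fc * T) + 2), length(t) - 1)
  stats::smooth.spline(t, y, df = df)
}

#' Mean-squared displacement of a smoothed track
#'
#' @param smoothed a [SmoothedTrack-class]
#' @param lags lag times (s) at which to evaluate the MSD
#' @return data.frame `lag`, `msd` (um^2)
#' @export
trackMSD <- function(smoothed, lags = NULL) {
  t <- smoothed@t
  dt <- median(diff(t))
  if (is.null(lags)) lags <- dt * unique(round(2^seq(0, log2((length(t) - 1) / 2), length.out = 12)))
  p <- smoothed@pos
  msd <- vapply(lags, function(lg) {
    k <- max(1L, round(lg / dt))
    if (k >= nrow(p)) return(NA_real_)
    d <- p[-(1:k), , drop = FALSE] - p[seq_len(nrow(p) - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  data.frame(lag = lags, msd = msd)[is.finite(msd), ]
}

#' Classify a track as motile or not
#'
#' A swimming cell's mean-squared displacement grows ballistically
#' (slope ~ 2 on log-log axes) while a particle moving by Brownian motion
#' alone is diffusive (slope ~ 1).  A track is motile when the short-time
#' log-log MSD slope exceeds `slopeThreshold` and the MSD at 2 s exceeds
#' `msd2sThreshold`.
#'
#' @param smoothed a [SmoothedTrack-class] of duration at least 2 s
#' @param slopeThreshold log-log slope threshold (default 1.5)
#' @param msd2sThreshold MSD(2 s) threshold (um^2, default 25)
#' @param slopeLagRange lag window (s) over which the slope is fitted
#' @return logical
#' @export
isMotile <- function(smoothed, slopeThreshold = 1.5, msd2sThreshold = 25,
                     slopeLagRange = c(0.2, 1.0)) {
  if (diff(range(smoothed@t)) < 2)
    stop("track duration must be at least 2 s")
  dt <- median(diff(smoothed@t))
  lags <- seq(max(dt, slopeLagRange[1]), slopeLagRange[2], by = 2 * dt)
  m <- trackMSD(smoothed, lags)
  m <- m[m$msd > 0, ]
  if (nrow(m) < 3) return(FALSE)
  slope <- stats::coef(lm(log(msd) ~ log(lag), data = m))[2]
  msd2 <- trackMSD(smoothed, 2)$msd
  isTRUE(slope > slopeThreshold && msd2 > msd2sThreshold)
}

#' Detect reorientation events on a smoothed track
#'
#' Scans the angular-speed series for local maxima above `threshold`
#' (default 5 degrees/s).  The series is first smoothed with a short
#' (~0.1 s) moving average so sample-scale ripples of the spline derivative
#' do not register as separate maxima; physical reorientations are much
#' wider and unaffected.  Events closer than `minSeparation` are merged
#' (stronger peak wins), so a single physical turn is never counted twice.
#' The turning angle of each event compares the swimming direction
#' `window` seconds before the peak with the direction `window` seconds
#' after; a pause followed by resumed swimming in the same direction
#' therefore yields an angle near zero.
#'
#' @param smoothed a [SmoothedTrack-class]
#' @param threshold d(theta)/dt threshold (degrees/s)
#' @param window half-window for the turning angle (s, default 0.25)
#' @param minSeparation minimum event spacing (s, default 0.5 = twice the
#'   angle window, so one physical turn is not counted twice)
#' @return data.frame `time` (s), `angle` (degrees in `[0, 180]`)
#' @export
detectReorientations <- function(smoothed, threshold = 5, window = 0.25,
                                 minSeparation = 0.5) {
  t <- smoothed@t
  if (diff(range(t)) <= 2 * window)
    stop("track must be longer than twice the angle window")
  dt <- median(diff(t))
  w <- max(1L, round(0.1 / dt))
  if (w %% 2 == 0) w <- w + 1L
  a <- as.numeric(stats::filter(smoothed@angSpeed, rep(1 / w, w),
                                sides = 2))
  edge <- is.na(a)
  a[edge] <- smoothed@angSpeed[edge]
  n <- length(a)
  peak <- which(a > threshold &
                a >= c(-Inf, a[-n]) & a >= c(a[-1], Inf))
  # events need the +-window inside the track
  peak <- peak[t[peak] - window >= t[1] & t[peak] + window <= t[n]]
  if (!length(peak))
    return(data.frame(time = numeric(), angle = numeric()))
  # enforce minimum separation, strongest first
  peak <- peak[order(-a[peak])]
  sel <- integer()
  for (p in peak)
    if (!length(sel) || all(abs(t[p] - t[sel]) >= minSeparation))
      sel <- c(sel, p)
  sel <- sort(sel)
  dirAt <- function(tt) {
    i <- which.min(abs(t - tt))
    smoothed@dir[i, ]
  }
  ang <- vapply(sel, function(p) {
    d1 <- dirAt(t[p] - window)
    d2 <- dirAt(t[p] + window)
    acos(pmin(1, pmax(-1, sum(d1 * d2)))) * 180 / pi
  }, numeric(1))
  data.frame(time = t[sel], angle = ang)
}

#' Run durations between reorientation events
#'
#' @param events data.frame with a time-sorted `time` column (one track's
#'   events), or a list of such data.frames (one per track)
#' @return numeric vector of inter-event intervals (s); tracks with fewer
#'   than two events contribute nothing
#' @export
runDurations <- function(events) {
  if (is.data.frame(events)) events <- list(events)
  unlist(lapply(events, function(e) {
    if (nrow(e) < 2) return(numeric())
    diff(sort(e$time))
  }))
}

#' Run-tumble summary over a set of tracks
#'
#' Full per-track pipeline: spline smoothing, motility classification,
#' reorientation detection; then pooled normalized histograms (relative
#' counts) of run durations, instantaneous speeds and turning angles over
#' the motile tracks.
#'
#' @param tracks data.frame `trackId`, `t`, `x`, `y`, `z` or a list of
#'   per-track data.frames
#' @param sigmaXY,sigmaZ localization noise passed to [smoothTrack()]
#' @param threshold,window reorientation detection settings
#' @param runBin,speedBin,angleBin histogram bin widths (s, um/s, degrees)
#' @param motileOnly drop non-motile tracks (default TRUE)
#' @return a [MotilitySummary-class]
#' @export
summarizeMotility <- function(tracks, sigmaXY = 0.5, sigmaZ = 1.0,
                              threshold = 5, window = 0.25, runBin = 0.5,
                              speedBin = 2, angleBin = 10,
                              motileOnly = TRUE) {
  if (is.data.frame(tracks)) tracks <- split(tracks, tracks$trackId)
  if (!length(tracks)) {
    warning("no tracks supplied; returning an empty summary")
    empty <- data.frame(mid = numeric(), count = integer(), p = numeric())
    return(new("MotilitySummary", runHist = empty, speedHist = empty,
               angleHist = empty, nTracks = 0L, nMotile = 0L, nEvents = 0L))
  }
  runs <- numeric(); speeds <- numeric(); angles <- numeric()
  nMotile <- 0L; nEvents <- 0L
  for (tr in tracks) {
    sm <- tryCatch(smoothTrack(tr, sigmaXY, sigmaZ), warning = function(w) NULL)
    if (is.null(sm)) next
    if (motileOnly && diff(range(sm@t)) >= 2 && !isMotile(sm)) next
    nMotile <- nMotile + 1L
    ev <- detectReorientations(sm, threshold = threshold, window = window)
    nEvents <- nEvents + nrow(ev)
    runs <- c(runs, runDurations(ev))
    speeds <- c(speeds, sm@speed)
    angles <- c(angles, ev$angle)
  }
  if (nMotile == 0L) warning("no motile tracks after filtering")
  new("MotilitySummary",
      runHist = .relHist(runs, runBin),
      speedHist = .relHist(speeds, speedBin),
      angleHist = .relHist(angles, angleBin, hi = 180),
      nTracks = length(tracks), nMotile = nMotile, nEvents = nEvents)
}

# normalized histogram (relative counts) with fixed-width bins from 0
.relHist <- function(x, width, hi = NULL) {
  if (!length(x))
    return(data.frame(mid = numeric(), count = integer(), p = numeric()))
  top <- if (is.null(hi)) (floor(max(x) / width) + 1) * width else hi
  breaks <- seq(0, top, by = width)
  h <- hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  data.frame(mid = h$mids, count = h$counts, p = h$counts / sum(h$counts))
}
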