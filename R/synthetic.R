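# Synthetic-data generators: run-tumble swimmers with the acquisition
# statistics of the holographic tracking experiments, point-scatterer
# hologram stacks, and the strain composition fixtures.

#' Generate synthetic run-tumble tracks with ground truth
#'
#' Simulates cells swimming with piecewise-constant heading: run segments at
#' a per-track speed drawn from a two-component mixture, reorientation
#' events arriving as a Poisson process at `tumbleRate`, turning angles
#' drawn from a broad law with a near-reversal component, plus rotational
#' diffusion of the heading and translational Brownian motion.  Positions
#' are sampled at the frame rate and localization noise (0.5 um lateral,
#' 1 um axial by default) is added, matching the 50 Hz / 60 s acquisition
#' the generator emulates.  The ground-truth event log supports closed-loop
#' recovery tests.
#'
#' @param params a [RunTumbleParams-class]
#' @param nTracks number of tracks
#' @param seed integer seed for reproducibility (`NULL` leaves the RNG
#'   state alone)
#' @return list with `tracks` (data.frame `trackId`, `t`, `x`, `y`, `z`),
#'   `truth` (data.frame `trackId`, `time`, `angle` of true reorientation
#'   events), `speeds` (true run speed per track) and `params`
#' @export
genRunTumbleTracks <- function(params = RunTumbleParams(), nTracks = 10,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / params@frameRate
  nf <- round(params@duration * params@frameRate) + 1L
  tgrid <- (seq_len(nf) - 1) * dt
  allTracks <- vector("list", nTracks)
  allEvents <- vector("list", nTracks)
  speeds <- numeric(nTracks)
  for (tr in seq_len(nTracks)) {
    comp <- sample.int(2L, 1L, prob = params@speedWeights)
    v <- max(0, rnorm(1, params@speedMeans[comp], params@speedSds[comp]))
    speeds[tr] <- v
    # tumble times over the duration
    tev <- numeric()
    if (params@tumbleRate > 0) {
      tt <- 0
      repeat {
        tt <- tt + rexp(1, params@tumbleRate)
        if (tt >= params@duration) break
        tev <- c(tev, tt)
      }
    }
    angles <- vapply(tev, function(e) .drawTurnAngle(params), numeric(1))
    n <- .randomUnit()
    pos <- matrix(0, nf, 3)
    evPtr <- 1L
    sigRot <- sqrt(2 * params@rotDiff * dt)
    sigTrans <- sqrt(2 * params@transDiff * dt)
    for (i in 2:nf) {
      t0 <- tgrid[i - 1]; t1 <- tgrid[i]
      # any tumbles inside this frame interval?
      while (evPtr <= length(tev) && tev[evPtr] <= t1) {
        n <- .rotateByAngle(n, angles[evPtr] * pi / 180)
        evPtr <- evPtr + 1L
      }
      if (sigRot > 0) {
        n <- n + sigRot * .randomPerp(n) * rnorm(1) +
          sigRot * .randomPerp(n) * rnorm(1)
        n <- n / sqrt(sum(n^2))
      }
      pos[i, ] <- pos[i - 1, ] + v * n * (t1 - t0) + sigTrans * rnorm(3)
    }
    noisy <- pos + cbind(rnorm(nf, 0, params@sigmaXY),
                         rnorm(nf, 0, params@sigmaXY),
                         rnorm(nf, 0, params@sigmaZ))
    allTracks[[tr]] <- data.frame(trackId = tr, t = tgrid,
                                  x = noisy[, 1], y = noisy[, 2],
                                  z = noisy[, 3])
    allEvents[[tr]] <- if (length(tev))
      data.frame(trackId = tr, time = tev, angle = angles)
    else data.frame(trackId = integer(), time = numeric(), angle = numeric())
  }
  list(tracks = do.call(rbind, allTracks),
       truth = do.call(rbind, allEvents),
       speeds = speeds, params = params)
}

# turning angle law: broad component (Beta(2,2) over [0,180]) plus a
# near-reversal Gaussian at 160 +- 15 degrees
.drawTurnAngle <- function(params) {
  if (runif(1) < params@angleBroadWeight) 180 * rbeta(1, 2, 2)
  else min(180, max(0, rnorm(1, 160, 15)))
}

.randomUnit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

.randomPerp <- function(n) {
  v <- rnorm(3)
  v <- v - sum(v * n) * n
  v / sqrt(sum(v^2))
}

# rotate unit vector n by angle theta about a uniformly random axis
# perpendicular to n (uniform azimuth)
.rotateByAngle <- function(n, theta) {
  p <- .randomPerp(n)
  cos(theta) * n + sin(theta) * p
}

#' Generate a synthetic point-scatterer hologram stack
#'
#' Forward counterpart of [rsBackpropagate()]: each point scatterer is a
#' small Gaussian amplitude at its axial plane, propagated to the detector
#' with the conjugate angular-spectrum kernel; the recorded intensity is
#' `|1 + a E_s|^2` plus Gaussian shot-like noise.  Serves as the round-trip
#' fixture for the reconstruction and localization stages.
#'
#' @param positions data.frame `frame`, `x`, `y`, `z` (um; x, y relative to
#'   the image center, z the distance from the detector plane)
#' @param nPixels image size (square)
#' @param pixelPitch um/px
#' @param wavelength vacuum wavelength (um)
#' @param medium refractive index
#' @param amplitude scattering amplitude relative to the unit background
#' @param spotSigma lateral extent of a scatterer (px)
#' @param noise additive Gaussian noise sd on the intensity
#' @param frameRate Hz (metadata only)
#' @param seed optional RNG seed for the noise
#' @return a [FrameStack-class]
#' @export
genPointHologram <- function(positions, nPixels = 256,
                             pixelPitch = 1400 / 1024, wavelength = 0.642,
                             medium = 1.33, amplitude = 0.2, spotSigma = 1,
                             noise = 0.005, frameRate = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frames <- if (nrow(positions)) sort(unique(positions$frame)) else 1L
  nT <- max(frames, 1L)
  out <- array(1, c(nPixels, nPixels, nT))
  kg <- .kzGrid(nPixels, nPixels, wavelength, pixelPitch, medium)
  ax <- ((seq_len(nPixels) - 1) - nPixels / 2) * pixelPitch
  for (fr in seq_len(nT)) {
    pts <- positions[positions$frame == fr, , drop = FALSE]
    if (!nrow(pts)) {
      img <- matrix(1, nPixels, nPixels)
    } else {
      field <- matrix(0i, nPixels, nPixels)
      for (r in seq_len(nrow(pts))) {
        g <- exp(-((outer(ax - pts$y[r], ax - pts$x[r], function(a, b)
          a^2 + b^2)) / (2 * (spotSigma * pixelPitch)^2)))
        # propagate from plane z to the detector: conjugate kernel
        H <- exp(-1i * pts$z[r] * kg$dkz)
        H[!kg$prop] <- 0i
        field <- field + stats::fft(stats::fft(g) * H, inverse = TRUE) /
          (nPixels^2)
      }
      img <- Mod(1 + amplitude * field)^2
    }
    if (noise > 0) img <- img + matrix(rnorm(nPixels^2, 0, noise),
                                       nPixels, nPixels)
    out[, , fr] <- img
  }
  FrameStack(out, pixelPitch = pixelPitch, frameRate = frameRate,
             wavelength = wavelength, medium = medium)
}

#' Named composition fixtures for the studied strains
#'
#' Proximal-segment fractions measured for the strains: wild-type-like
#' FlaAB (proximal FlaA 17% on average), FlaA-only, FlaB-only, FlaAAB
#' (proximal FlaA raised to 24%), and the reversed-order FlaBA (proximal
#' FlaB 6.8%) and FlaBBA (proximal FlaB 8.1%).
#'
#' @param Lc contour length (um)
#' @return named list of [CompositionProfile-class] objects
#' @export
strainFixtures <- function(Lc = 6) {
  list(
    FlaAB  = compositionProfile(0.17, Lc = Lc, order = "flaA-proximal"),
    FlaAonly = compositionProfile(1, Lc = Lc),
    FlaBonly = compositionProfile(0, Lc = Lc),
    FlaAAB = compositionProfile(0.24, Lc = Lc, order = "flaA-proximal"),
    FlaBA  = compositionProfile(1 - 0.068, Lc = Lc, order = "flaB-proximal"),
    FlaBBA = compositionProfile(1 - 0.081, Lc = Lc, order = "flaB-proximal"))
}
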