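# Digital inline holography: background normalization, Rayleigh-Sommerfeld
# (angular-spectrum) back-propagation, Sobel-type 3D localization and
# track linking.

#' Normalize a hologram stack by its static background
#'
#' The per-pixel temporal median of the stack estimates the static
#' background (illumination profile plus stationary speckle); every frame is
#' divided by it.  The median is robust against transient objects and
#' single-frame outliers, which a mean would smear into the background.
#' Pixels whose background is zero are masked (`NA`) with a warning.
#'
#' @param stack a [FrameStack-class] with at least 3 frames
#' @return a [FrameStack-class] of normalized frames (background ~ 1);
#'   the background image is attached as attribute `"background"` of the
#'   data array
#' @export
preprocessStack <- function(stack) {
  d <- stack@data
  if (dim(d)[3] < 3) stop("need at least 3 frames to estimate the background")
  bg <- apply(d, c(1, 2), median)
  zero <- bg == 0
  if (any(zero)) {
    warning(sum(zero), " background pixel(s) are zero; masked as NA")
    bg[zero] <- NA_real_
  }
  out <- sweep(d, c(1, 2), bg, "/")
  attr(out, "background") <- bg
  new("FrameStack", data = out, pixelPitch = stack@pixelPitch,
      frameRate = stack@frameRate, wavelength = stack@wavelength,
      medium = stack@medium)
}

# angular-spectrum transfer function phases: kz - k (carrier removed), for a
# ny x nx grid; returns the matrix of kz-k (1/um) and the propagating mask
.kzGrid <- function(ny, nx, wavelength, pixelPitch, medium) {
  k <- 2 * pi * medium / wavelength
  fy <- c(0:(ny %/% 2), -((ceiling(ny / 2) - 1):1)) / (ny * pixelPitch)
  fx <- c(0:(nx %/% 2), -((ceiling(nx / 2) - 1):1)) / (nx * pixelPitch)
  ky2 <- (2 * pi * fy)^2
  kx2 <- (2 * pi * fx)^2
  q2 <- outer(ky2, kx2, "+")
  arg <- k^2 - q2
  prop <- arg > 0
  kz <- sqrt(pmax(arg, 0))
  list(dkz = kz - k, prop = prop)
}

# spatial bandpass mask passing features between band[1] and band[2] pixels:
# raised-cosine annulus in |f| (cycles/px) between 1/band[2] and 0.9/band[1]
.bandMask <- function(ny, nx, band) {
  fy <- c(0:(ny %/% 2), -((ceiling(ny / 2) - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((ceiling(nx / 2) - 1):1)) / nx
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  fLo <- 1 / band[2]
  fHi <- 0.9 / band[1]
  wLo <- 0.5 * fLo
  wHi <- 0.2 * fHi
  up <- pmin(pmax((fr - fLo + wLo) / wLo, 0), 1)
  dn <- pmin(pmax((fHi - fr) / wHi, 0), 1)
  m <- (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * dn))
  m[1, 1] <- 0   # remove the DC term (uniform background)
  m
}

#' Rayleigh-Sommerfeld back-propagation of a hologram
#'
#' Numerically refocuses a normalized hologram to a set of axial planes via
#' the angular-spectrum transfer function
#' \eqn{H(q; z) = \exp[i z (\sqrt{k^2 - q^2} - k)]} (the axial carrier
#' \eqn{e^{ikz}} is removed so the phase of the refocused field is referenced
#' to the detector plane).  Evanescent components are suppressed.  A spatial
#' bandpass retaining features between `band[1]` and `band[2]` pixels is
#' applied during reconstruction; `band = NULL` disables it.
#'
#' @param frame 2D numeric matrix (a normalized hologram, background ~ 1) or
#'   complex matrix (a field)
#' @param zPlanes axial reconstruction distances (um), positive toward the
#'   sample
#' @param wavelength vacuum wavelength (um)
#' @param pixelPitch lateral sampling (um/px)
#' @param band feature-size band in pixels, default `c(2, 30)`
#' @param medium refractive index
#' @return a [HoloVolume-class]
#' @export
rsBackpropagate <- function(frame, zPlanes, wavelength = 0.642,
                            pixelPitch = 1400 / 1024, band = c(2, 30),
                            medium = 1.33) {
  if (wavelength <= 0 || pixelPitch <= 0)
    stop("config error: wavelength and pixelPitch must be positive")
  ny <- nrow(frame); nx <- ncol(frame)
  # scattered-field estimate: hologram contrast about the unit background
  b <- if (is.complex(frame)) frame else frame - mean(frame)
  B <- stats::fft(b)
  if (!is.null(band)) B <- B * .bandMask(ny, nx, band)
  kg <- .kzGrid(ny, nx, wavelength, pixelPitch, medium)
  out <- array(0i, c(ny, nx, length(zPlanes)))
  for (j in seq_along(zPlanes)) {
    H <- exp(1i * zPlanes[j] * kg$dkz)
    H[!kg$prop] <- 0i
    out[, , j] <- stats::fft(B * H, inverse = TRUE) / (ny * nx)
  }
  new("HoloVolume", field = out, zPlanes = zPlanes, pixelPitch = pixelPitch)
}

# lateral 3x3 binomial smoothing of a matrix (edge-replicated)
.smooth3 <- function(m) {
  pad <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  i <- 2:(nrow(pad) - 1); j <- 2:(ncol(pad) - 1)
  (4 * pad[i, j] +
   2 * (pad[i - 1, j] + pad[i + 1, j] + pad[i, j - 1] + pad[i, j + 1]) +
   pad[i - 1, j - 1] + pad[i - 1, j + 1] + pad[i + 1, j - 1] +
   pad[i + 1, j + 1]) / 16
}

#' Localize point-like cells in a reconstructed volume
#'
#' Applies a Sobel-type axial-gradient filter to the refocused field:
#' with the axial carrier removed, the phase of the scattered field rotates
#' fastest at focus (the axial phase anomaly), so the magnitude of the
#' complex z derivative -- central differences with 3x3 lateral binomial
#' smoothing, a 3D Sobel kernel -- peaks at the particle position.  Local
#' maxima of the response above `threshold` (default: mean + 5 sd of the
#' response volume, with a relative floor at 20% of the strongest response)
#' are reported with sub-voxel refinement by quadratic interpolation in
#' x, y and z.
#'
#' @param volume a [HoloVolume-class]
#' @param threshold detection threshold on the response; `NULL` for the
#'   adaptive default
#' @param minSeparation minimum lateral distance between detections (um);
#'   of a pair closer than this in the x-y plane only the stronger is kept.
#'   Residual axial sidelobes of a scatterer share its lateral position, so
#'   the exclusion is cylindrical rather than spherical.
#' @return data.frame with `x`, `y`, `z` (um; x, y relative to the image
#'   center) and `response`; zero rows when nothing is found
#' @export
localizeCells <- function(volume, threshold = NULL, minSeparation = 15) {
  f <- volume@field
  ny <- dim(f)[1]; nx <- dim(f)[2]; nz <- dim(f)[3]
  if (nz < 3) stop("need at least 3 z planes for the axial gradient")
  resp <- array(0, dim(f))
  for (j in 2:(nz - 1))
    resp[, , j] <- .smooth3(Re(f[, , j + 1] - f[, , j - 1]))^2 +
      .smooth3(Im(f[, , j + 1] - f[, , j - 1]))^2
  resp <- sqrt(resp)
  if (is.null(threshold))
    threshold <- max(mean(resp) + 5 * sd(resp), 0.2 * max(resp))
  hits <- which(resp > threshold, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      response = numeric()))
  # local maxima over the 3x3x3 neighborhood
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    iy <- hits[r, 1]; ix <- hits[r, 2]; iz <- hits[r, 3]
    ys <- max(1, iy - 1):min(ny, iy + 1)
    xs <- max(1, ix - 1):min(nx, ix + 1)
    zs <- max(1, iz - 1):min(nz, iz + 1)
    keep[r] <- resp[iy, ix, iz] >= max(resp[ys, xs, zs])
  }
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      response = numeric()))
  # sub-voxel quadratic refinement
  qpeak <- function(a, b, cc) {
    den <- a - 2 * b + cc
    if (abs(den) < 1e-300) 0 else max(-0.5, min(0.5, 0.5 * (a - cc) / den))
  }
  px <- volume@pixelPitch
  zs <- volume@zPlanes
  out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    response = numeric(0))
  for (r in seq_len(nrow(hits))) {
    iy <- hits[r, 1]; ix <- hits[r, 2]; iz <- hits[r, 3]
    dy <- if (iy > 1 && iy < ny)
      qpeak(resp[iy - 1, ix, iz], resp[iy, ix, iz], resp[iy + 1, ix, iz]) else 0
    dx <- if (ix > 1 && ix < nx)
      qpeak(resp[iy, ix - 1, iz], resp[iy, ix, iz], resp[iy, ix + 1, iz]) else 0
    dz <- if (iz > 1 && iz < nz)
      qpeak(resp[iy, ix, iz - 1], resp[iy, ix, iz], resp[iy, ix, iz + 1]) else 0
    zstep <- if (iz < nz) zs[iz + 1] - zs[iz] else zs[iz] - zs[iz - 1]
    out <- rbind(out, data.frame(
      x = (ix - 1 - (nx / 2)) * px + dx * px,
      y = (iy - 1 - (ny / 2)) * px + dy * px,
      z = zs[iz] + dz * zstep,
      response = resp[iy, ix, iz]))
  }
  # enforce minimum lateral separation (keep stronger of close pairs)
  out <- out[order(-out$response), ]
  sel <- rep(TRUE, nrow(out))
  if (nrow(out) > 1) {
    for (r in 2:nrow(out)) {
      d <- sqrt((out$x[seq_len(r - 1)] - out$x[r])^2 +
                (out$y[seq_len(r - 1)] - out$y[r])^2)
      if (any(d[sel[seq_len(r - 1)]] < minSeparation)) sel[r] <- FALSE
    }
  }
  out <- out[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link per-frame localizations into tracks
#'
#' Greedy nearest-neighbor assignment frame to frame: each active track is
#' extended by its closest unclaimed detection within `maxStep` um (scaled
#' by the number of frames skipped); detections left unmatched start new
#' tracks, and tracks missing a detection survive up to `maxGap` frames,
#' with bridged gaps filled by linear interpolation and flagged.
#'
#' @param detections data.frame with columns `frame`, `x`, `y`, `z` (and
#'   optionally `t`); frames need not be consecutive
#' @param maxStep maximum displacement per frame (um)
#' @param maxGap maximum number of missed frames bridged
#' @param frameRate used to fill the `t` column when absent (Hz)
#' @return data.frame `trackId`, `frame`, `t`, `x`, `y`, `z`,
#'   `interpolated`
#' @export
linkTracks <- function(detections, maxStep = 5, maxGap = 1, frameRate = 50) {
  if (!nrow(detections))
    return(data.frame(trackId = integer(), frame = integer(), t = numeric(),
                      x = numeric(), y = numeric(), z = numeric(),
                      interpolated = logical()))
  if (is.null(detections$t)) detections$t <- (detections$frame - 1) / frameRate
  frames <- sort(unique(detections$frame))
  tracks <- list()   # each: list(rows = data.frame, lastFrame)
  nextId <- 1L
  for (fr in frames) {
    det <- detections[detections$frame == fr, , drop = FALSE]
    used <- rep(FALSE, nrow(det))
    active <- which(vapply(tracks, function(tr)
      fr - tr$lastFrame <= maxGap + 1L, logical(1)))
    if (length(active)) {
      # distance of every active track end to every detection
      cand <- expand.grid(a = active, d = seq_len(nrow(det)))
      last <- do.call(rbind, lapply(tracks[cand$a], function(tr)
        unlist(tr$rows[nrow(tr$rows), c("x", "y", "z")])))
      gap <- vapply(tracks[cand$a], function(tr) fr - tr$lastFrame, numeric(1))
      cand$dist <- sqrt((last[, 1] - det$x[cand$d])^2 +
                        (last[, 2] - det$y[cand$d])^2 +
                        (last[, 3] - det$z[cand$d])^2)
      cand <- cand[cand$dist <= maxStep * gap, , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      claimed <- logical(length(tracks))
      for (r in seq_len(nrow(cand))) {
        a <- cand$a[r]; d <- cand$d[r]
        if (claimed[a] || used[d]) next
        claimed[a] <- TRUE; used[d] <- TRUE
        tr <- tracks[[a]]
        gapN <- fr - tr$lastFrame - 1L
        if (gapN > 0) {   # bridge the gap by interpolation
          lastRow <- tr$rows[nrow(tr$rows), ]
          for (g in seq_len(gapN)) {
            wgt <- g / (gapN + 1)
            tr$rows <- rbind(tr$rows, data.frame(
              frame = lastRow$frame + g,
              t = lastRow$t + g / frameRate,
              x = lastRow$x + wgt * (det$x[d] - lastRow$x),
              y = lastRow$y + wgt * (det$y[d] - lastRow$y),
              z = lastRow$z + wgt * (det$z[d] - lastRow$z),
              interpolated = TRUE))
          }
        }
        tr$rows <- rbind(tr$rows, data.frame(
          frame = fr, t = det$t[d], x = det$x[d], y = det$y[d], z = det$z[d],
          interpolated = FALSE))
        tr$lastFrame <- fr
        tracks[[a]] <- tr
      }
    }
    for (d in which(!used)) {
      tracks[[length(tracks) + 1L]] <- list(
        rows = data.frame(frame = fr, t = det$t[d], x = det$x[d],
                          y = det$y[d], z = det$z[d], interpolated = FALSE),
        lastFrame = fr)
    }
  }
  out <- do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(trackId = i, tracks[[i]]$rows)))
  rownames(out) <- NULL
  out
}
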