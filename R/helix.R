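#' Rest rotational strain of a helix
#'
#' Maps a helix geometry to the constant rotational strain vector
#' \eqn{\Omega_0 = (\kappa, 0, \sigma\tau)} of a rod whose material frame,
#' integrated along arclength, traces that helix.  With \eqn{p = P/(2\pi)},
#' curvature \eqn{\kappa = R/(R^2+p^2)} and torsion
#' \eqn{\tau = p/(R^2+p^2)}; a left-handed helix carries negative rest
#' torsion (\eqn{\sigma = -1}).
#'
#' @param geometry a [HelixGeometry-class]
#' @return numeric strain vector `c(Omega1, Omega2, Omega3)` in 1/um
#' @examples
#' helixToStrain(HelixGeometry(0.175, 1.18))  # ~ (2.656, 0, -2.850)
#' @export
helixToStrain <- function(geometry) {
  stopifnot(is(geometry, "HelixGeometry"))
  validObject(geometry)
  R <- geometry@radius
  p <- geometry@pitch / (2 * pi)
  s <- if (geometry@handedness == "left") -1 else 1
  denom <- R^2 + p^2
  c(R / denom, 0, s * p / denom)
}

#' Contour length of one helical turn
#'
#' \eqn{l = \sqrt{4\pi^2 R^2 + P^2}}; enters the slender-body logarithm of
#' the resistive-force-theory drag coefficients.
#'
#' @param geometry a [HelixGeometry-class]
#' @return length of one turn (um)
#' @export
turnLength <- function(geometry) {
  stopifnot(is(geometry, "HelixGeometry"))
  sqrt(4 * pi^2 * geometry@radius^2 + geometry@pitch^2)
}

#' Number of helical turns of a filament
#'
#' @param geometry a [HelixGeometry-class]
#' @param Lc contour length (um)
#' @return `Lc / turnLength(geometry)`
#' @export
helixTurns <- function(geometry, Lc = 6) Lc / turnLength(geometry)

#' Integrate a material frame along arclength at constant strain
#'
#' Generates the space curve and frames of a rod with constant rotational
#' strain `omega0`: frame \eqn{i} is frame \eqn{i-1} composed with the
#' rotation \eqn{\exp(h [\Omega_0]_\times)}, and beads advance by
#' \eqn{h\, e_3}.  This is the exact inverse of [helixToStrain()] in the
#' sense that the generated bead cloud is a discrete helix with the original
#' radius and pitch.
#'
#' @param omega0 strain vector (1/um)
#' @param h arclength step (um)
#' @param n number of segments
#' @param q0 initial frame quaternion (default: axis-aligned, see Details)
#' @details With the default `q0`, the helix axis is the lab z axis and the
#'   filament advances toward +z regardless of handedness.
#' @return list with `positions` ((n+1) x 3), `quats` (n x 4) and `q0`
#' @export
frameIntegrateHelix <- function(omega0, h, n, q0 = NULL) {
  if (is.null(q0)) q0 <- .helixBaseFrame(omega0)
  dq <- .qexp(h * omega0)
  quats <- matrix(0, n, 4)
  pos <- matrix(0, n + 1, 3)
  q <- q0
  for (i in seq_len(n)) {
    q <- .qnormalize(.qmul(q, dq))
    quats[i, ] <- q
    e3 <- .qrotmat(q)[, 3]
    pos[i + 1, ] <- pos[i, ] + h * e3
  }
  list(positions = pos, quats = quats, q0 = q0)
}

# Base frame whose rotation maps the (constant, body-fixed) helix axis
# omega0/|omega0| onto sign(Omega3) * z, so the filament grows toward +z.
.helixBaseFrame <- function(omega0) {
  nu <- sqrt(sum(omega0^2))
  if (nu < 1e-12) return(c(1, 0, 0, 0))
  axisBody <- omega0 / nu
  target <- c(0, 0, if (omega0[3] < 0) -1 else 1)
  # want R(q) %*% axisBody == target  => q rotates axisBody to target
  .qbetween(axisBody, target)
}

#' Fit helix parameters to a bead cloud
#'
#' Independent geometric measurement used to verify constructed filaments:
#' assumes the helix axis is the z axis, fits the circle traced in the
#' xy plane (Kasa least-squares) and regresses the unwrapped azimuthal phase
#' against z.
#'
#' @param positions `m x 3` matrix of points on a helix with axis z
#' @return list with `radius`, `pitch` (um) and `handedness`
#' @export
helixMetrics <- function(positions) {
  x <- positions[, 1]; y <- positions[, 2]; z <- positions[, 3]
  # Kasa circle fit: minimize |x^2+y^2 - 2ax - 2by - c|
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  ph <- atan2(y - cy, x - cx)
  ph <- ph + cumsum(c(0, round(-diff(ph) / (2 * pi))) * 2 * pi)  # unwrap
  fit <- stats::lm.fit(cbind(1, z), ph)
  slope <- fit$coefficients[2]                                   # rad / um
  list(radius = unname(r), pitch = unname(abs(2 * pi / slope)),
       handedness = if (slope < 0) "left" else "right")
}
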