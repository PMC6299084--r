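# Resistive-force-theory drag coefficients and the local drag response.

#' Per-unit-length friction coefficients of a helical filament segment
#'
#' @slot gammaPerp friction for motion perpendicular to the centerline
#'   (pN s / um^2)
#' @slot gammaPar tangential friction (pN s / um^2); always smaller than
#'   `gammaPerp`
#' @slot gammaRot rotational (axial spin) friction (pN s)
#' @slot turnLength contour length of one helical turn (um)
#' @export
setClass("FrictionSet",
  representation(gammaPerp = "numeric", gammaPar = "numeric",
                 gammaRot = "numeric", turnLength = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@gammaPerp > object@gammaPar && object@gammaPar > 0))
      msg <- c(msg, "need gammaPerp > gammaPar > 0")
    if (object@gammaRot <= 0) msg <- c(msg, "gammaRot must be > 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FrictionSet", function(object) {
  cat(sprintf(paste0("FrictionSet: gammaPerp = %.4g, gammaPar = %.4g pN s/um^2, ",
                     "gammaRot = %.4g pN s (l = %.4g um)\n"),
              object@gammaPerp, object@gammaPar, object@gammaRot,
              object@turnLength))
})

#' Resistive-force-theory friction coefficients
#'
#' For a slender helical segment of filament radius `rF` in a fluid of
#' viscosity `eta`, with `l` the contour length of one helical turn:
#' \deqn{\gamma_\perp = \frac{4\pi\eta}{\ln(0.09\, l/r_F) + 1/2}, \quad
#'       \gamma_\| = \frac{2\pi\eta}{\ln(0.09\, l/r_F)}, \quad
#'       \gamma_r = 4\pi\eta r_F^2.}
#'
#' @param geometry a [HelixGeometry-class] (sets `l` through [turnLength()])
#' @param rF filament radius (um)
#' @param eta dynamic viscosity (pN s / um^2); water is 1e-3
#' @return a [FrictionSet-class]
#' @examples
#' frictionCoefficients(HelixGeometry(0.315, 1.91))
#' @export
frictionCoefficients <- function(geometry, rF = 0.01, eta = 1e-3) {
  if (rF <= 0 || eta <= 0)
    stop("parameter-domain error: rF and eta must be positive")
  l <- turnLength(geometry)
  lg <- log(0.09 * l / rF)
  if (lg <= 0)
    stop("parameter-domain error: 0.09 * l / rF must exceed 1 ",
         "(filament not slender enough for resistive force theory)")
  new("FrictionSet",
      gammaPerp = 4 * pi * eta / (lg + 0.5),
      gammaPar = 2 * pi * eta / lg,
      gammaRot = 4 * pi * eta * rF^2,
      turnLength = l)
}

#' Local drag response of the filament
#'
#' Resistive-force-theory drag on each segment for a given velocity field:
#' force per unit length
#' \eqn{-[\gamma_\| t t^T + \gamma_\perp (I - t t^T)]\, v} with `t` the local
#' tangent and `v` the segment midpoint velocity, plus the axial frame torque
#' \eqn{-\gamma_r \omega_{ax}} opposing spin about the tangent.  Coefficients
#' are evaluated per segment from the local flagellin's geometry.
#'
#' @param state a [FilamentState-class]
#' @param beadVelocities `(n+1) x 3` matrix (um/s)
#' @param spinRates length-n vector of axial spin rates (rad/s)
#' @param friction a single [FrictionSet-class] or a list of one per segment
#' @return list with `forcePerLength` (n x 3, pN/um), `segmentForces`
#'   (n x 3, pN, force per length times `h`) and `axialTorque` (n, pN um)
#' @export
dragResponse <- function(state, beadVelocities, spinRates, friction) {
  n <- nrow(state@quats)
  if (is(friction, "FrictionSet")) friction <- rep(list(friction), n)
  stopifnot(length(friction) == n, nrow(beadVelocities) == n + 1)
  fpl <- matrix(0, n, 3)
  tq <- numeric(n)
  for (i in seq_len(n)) {
    d <- state@positions[i + 1, ] - state@positions[i, ]
    t <- d / sqrt(sum(d^2))
    v <- (beadVelocities[i, ] + beadVelocities[i + 1, ]) / 2
    fr <- friction[[i]]
    vpar <- sum(v * t) * t
    fpl[i, ] <- -(fr@gammaPar * vpar + fr@gammaPerp * (v - vpar))
    tq[i] <- -fr@gammaRot * state@h * spinRates[i]
  }
  list(forcePerLength = fpl, segmentForces = fpl * state@h, axialTorque = tq)
}
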