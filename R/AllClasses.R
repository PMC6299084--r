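#' @import methods
NULL

# ---------------------------------------------------------------------------
# Geometry and material classes
# ---------------------------------------------------------------------------

#' Equilibrium helix geometry of a flagellin
#'
#' A flagellin polymer relaxes to a helical filament characterized by its
#' radius \eqn{R}, pitch \eqn{P} and handedness.  FlaA of
#' \emph{Shewanella putrefaciens} forms narrow elongated helices
#' (R = 0.175 um, P = 1.18 um), FlaB wider ones (R = 0.315 um, P = 1.91 um);
#' both are left-handed.
#'
#' @slot radius helix radius R (um), `>= 0` (0 = straight line)
#' @slot pitch helix pitch P (um), `> 0`
#' @slot handedness `"left"` or `"right"`
#' @export
setClass("HelixGeometry",
  representation(radius = "numeric", pitch = "numeric", handedness = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@radius) != 1 || !is.finite(object@radius) ||
        object@radius < 0)
      msg <- c(msg, "radius must be a single finite value >= 0")
    if (length(object@pitch) != 1 || !is.finite(object@pitch) ||
        object@pitch <= 0)
      msg <- c(msg, "pitch must be a single finite value > 0")
    if (!object@handedness %in% c("left", "right"))
      msg <- c(msg, "handedness must be 'left' or 'right'")
    if (length(msg)) msg else TRUE
  })

#' Construct a [HelixGeometry-class]
#'
#' @param radius helix radius (um)
#' @param pitch helix pitch (um); must be positive
#' @param handedness `"left"` (default, the native sense of the
#'   \emph{Shewanella} polar flagellum) or `"right"`
#' @return a `HelixGeometry` object
#' @examples
#' HelixGeometry(0.175, 1.18)   # FlaA
#' @export
HelixGeometry <- function(radius, pitch, handedness = "left") {
  new("HelixGeometry", radius = as.numeric(radius), pitch = as.numeric(pitch),
      handedness = match.arg(handedness, c("left", "right")))
}

setMethod("show", "HelixGeometry", function(object) {
  cat(sprintf("HelixGeometry: R = %.4g um, P = %.4g um, %s-handed\n",
              object@radius, object@pitch, object@handedness))
})

#' A flagellin and its polymorphic equilibrium states
#'
#' Each flagellin carries an ordered list of equilibrium helix geometries
#' (polymorphic states); the first is the native state the filament is built
#' in.  FlaA has a single known state; FlaB has two, the second being a
#' right-handed "curly" form reachable under strong torsional load.
#'
#' @slot name identifier, e.g. `"FlaA"`
#' @slot states list of [HelixGeometry-class] objects, at least one
#' @export
setClass("FlagellinSpec",
  representation(name = "character", states = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@states) < 1)
      msg <- c(msg, "at least one polymorphic state is required")
    if (!all(vapply(object@states, is, logical(1), "HelixGeometry")))
      msg <- c(msg, "all states must be HelixGeometry objects")
    if (length(msg)) msg else TRUE
  })

#' @rdname FlagellinSpec-class
#' @param name flagellin identifier
#' @param states list of [HelixGeometry-class] polymorphic states
#' @export
FlagellinSpec <- function(name, states) {
  if (is(states, "HelixGeometry")) states <- list(states)
  new("FlagellinSpec", name = name, states = states)
}

setMethod("show", "FlagellinSpec", function(object) {
  cat(sprintf("FlagellinSpec '%s' with %d polymorphic state(s)\n",
              object@name, length(object@states)))
  for (s in object@states) show(s)
})

#' Built-in flagellins
#'
#' `flaA()` returns the FlaA specification (single narrow left-handed state,
#' R = 0.175 um, P = 1.18 um).  `flaB()` returns FlaB with its native wide
#' left-handed state (R = 0.315 um, P = 1.91 um) and a second, right-handed
#' curly equilibrium state.  The curly-state geometry is not known
#' experimentally for this organism and is a configurable model choice
#' (defaults R = 0.14 um, P = 1.0 um).
#'
#' @param curlyRadius,curlyPitch geometry of the second FlaB state (um)
#' @return a [FlagellinSpec-class]
#' @export
flaA <- function() {
  FlagellinSpec("FlaA", list(HelixGeometry(0.175, 1.18, "left")))
}

#' @rdname flaA
#' @export
flaB <- function(curlyRadius = 0.14, curlyPitch = 1.0) {
  FlagellinSpec("FlaB", list(
    HelixGeometry(0.315, 1.91, "left"),
    HelixGeometry(curlyRadius, curlyPitch, "right")))
}

#' Elastic parameters of the filament
#'
#' @slot A bending rigidity (pN um^2)
#' @slot C torsional rigidity (pN um^2); the same A and C are used for all
#'   polymorphic states and both flagellins
#' @slot K stretching constant (pN) of the harmonic bond spring; `NA` means
#'   calibrate automatically so the maximum bond strain stays within 0.1%
#'   at the torque being simulated
#' @slot rF filament radius (um), enters the drag coefficients
#' @slot hookStiffness bending stiffness of the base (hook) junction
#'   (pN um / rad).  The flexible hook joining motor and filament is folded
#'   into the base boundary condition as a reduced bending stiffness of the
#'   proximal junction; the default 0.6 corresponds to a hook bending
#'   rigidity of ~3.6e-2 pN um^2 over a ~60 nm hook.  Torque about the
#'   filament axis is transmitted with the full torsional rigidity C.
#' @export
setClass("ElasticParams",
  representation(A = "numeric", C = "numeric", K = "numeric", rF = "numeric",
                 hookStiffness = "numeric"),
  prototype = prototype(A = 3.5, C = 3.5, K = NA_real_, rF = 0.01,
                        hookStiffness = 0.6),
  validity = function(object) {
    msg <- character()
    if (object@A <= 0 || object@C <= 0) msg <- c(msg, "A and C must be > 0")
    if (!is.na(object@K) && object@K <= 0) msg <- c(msg, "K must be > 0 or NA")
    if (object@rF <= 0) msg <- c(msg, "rF must be > 0")
    if (object@hookStiffness < 0)
      msg <- c(msg, "hookStiffness must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname ElasticParams-class
#' @param A,C bending and torsional rigidity (pN um^2)
#' @param K stretching constant (pN); `NA` = auto-calibrated
#' @param rF filament radius (um)
#' @param hookStiffness base-junction bending stiffness (pN um / rad)
#' @export
ElasticParams <- function(A = 3.5, C = 3.5, K = NA_real_, rF = 0.01,
                          hookStiffness = 0.6) {
  # the slot named "C" cannot be passed through new() directly (it would
  # partially match the Class argument), so fill slots explicitly
  obj <- new("ElasticParams")
  obj@A <- as.numeric(A); obj@C <- as.numeric(C)
  obj@K <- as.numeric(K); obj@rF <- as.numeric(rF)
  obj@hookStiffness <- as.numeric(hookStiffness)
  validObject(obj)
  obj
}

setMethod("show", "ElasticParams", function(object) {
  cat(sprintf("ElasticParams: A = %.3g pN um^2, C = %.3g pN um^2, K = %s, rF = %.3g um\n",
              object@A, object@C,
              if (is.na(object@K)) "auto" else sprintf("%.3g pN", object@K),
              object@rF))
})

#' Fluid parameters
#'
#' @slot eta dynamic viscosity (pN s / um^2); water is 1e-3.  Elevated
#'   viscosity media are modeled by scaling eta.
#' @export
setClass("FluidParams", representation(eta = "numeric"),
  validity = function(object)
    if (object@eta > 0) TRUE else "eta must be > 0")

#' @rdname FluidParams-class
#' @param eta dynamic viscosity (pN s / um^2)
#' @export
FluidParams <- function(eta = 1e-3) new("FluidParams", eta = eta)

# ---------------------------------------------------------------------------
# Composition of the filament
# ---------------------------------------------------------------------------

#' Arclength partition of the filament into flagellin segments
#'
#' The filament of contour length `Lc` is partitioned at `breakpoints`
#' (interior arclength positions) into cells, each assembled from one
#' flagellin.  Flagellins can be switched at continuous positions along the
#' filament.
#'
#' @slot Lc total contour length (um), default 6
#' @slot breakpoints strictly increasing interior arclength positions in
#'   (0, Lc); may be empty for a single-flagellin filament
#' @slot flagellins list of [FlagellinSpec-class], one per partition cell
#'   (length = `length(breakpoints) + 1`), ordered from base (motor) to tip
#' @export
setClass("CompositionProfile",
  representation(Lc = "numeric", breakpoints = "numeric", flagellins = "list"),
  validity = function(object) {
    msg <- character()
    if (object@Lc <= 0) msg <- c(msg, "Lc must be > 0")
    b <- object@breakpoints
    if (length(b) && (any(b <= 0) || any(b >= object@Lc) || is.unsorted(b, strictly = TRUE)))
      msg <- c(msg, "breakpoints must be strictly increasing within (0, Lc)")
    if (length(object@flagellins) != length(b) + 1L)
      msg <- c(msg, "need exactly length(breakpoints) + 1 flagellins")
    if (!all(vapply(object@flagellins, is, logical(1), "FlagellinSpec")))
      msg <- c(msg, "flagellins must be FlagellinSpec objects")
    if (length(msg)) msg else TRUE
  })

#' Two-flagellin composition with a proximal segment
#'
#' Convenience constructor for the compositions studied here: a proximal
#' (motor-side) segment of one flagellin followed by the other for the rest
#' of the filament.
#'
#' @param flaAFraction fraction of the contour length assigned to FlaA,
#'   in `[0, 1]`
#' @param Lc contour length (um)
#' @param order `"flaA-proximal"` (wild-type-like: FlaA at the base) or
#'   `"flaB-proximal"` (reversed order)
#' @param A,B the two [FlagellinSpec-class] objects
#' @return a [CompositionProfile-class]
#' @examples
#' compositionProfile(0.17)                         # wild-type-like
#' compositionProfile(0.932, order = "flaB-proximal")  # 6.8% proximal FlaB
#' @export
compositionProfile <- function(flaAFraction, Lc = 6,
                               order = c("flaA-proximal", "flaB-proximal"),
                               A = flaA(), B = flaB()) {
  order <- match.arg(order)
  stopifnot(flaAFraction >= 0, flaAFraction <= 1)
  if (order == "flaA-proximal") {
    first <- A; second <- B; firstLen <- flaAFraction * Lc
  } else {
    first <- B; second <- A; firstLen <- (1 - flaAFraction) * Lc
  }
  if (firstLen <= 0) {
    new("CompositionProfile", Lc = Lc, breakpoints = numeric(),
        flagellins = list(second))
  } else if (firstLen >= Lc) {
    new("CompositionProfile", Lc = Lc, breakpoints = numeric(),
        flagellins = list(first))
  } else {
    new("CompositionProfile", Lc = Lc, breakpoints = firstLen,
        flagellins = list(first, second))
  }
}

#' @rdname compositionProfile
#' @param Lc contour length (um)
#' @param breakpoints interior partition positions (um)
#' @param flagellins list of [FlagellinSpec-class], one per cell
#' @export
CompositionProfile <- function(Lc = 6, breakpoints = numeric(),
                               flagellins = list(flaB())) {
  new("CompositionProfile", Lc = Lc, breakpoints = as.numeric(breakpoints),
      flagellins = flagellins)
}

setMethod("show", "CompositionProfile", function(object) {
  edges <- c(0, object@breakpoints, object@Lc)
  cat(sprintf("CompositionProfile: Lc = %.3g um, %d cell(s), FlaA fraction %.3g\n",
              object@Lc, length(object@flagellins), flaAFraction(object)))
  for (i in seq_along(object@flagellins))
    cat(sprintf("  [%.3g, %.3g] um: %s\n", edges[i], edges[i + 1],
                object@flagellins[[i]]@name))
})

# ---------------------------------------------------------------------------
# Simulation state and configuration
# ---------------------------------------------------------------------------

#' Discretized filament state
#'
#' The filament is a string of `n + 1` beads joined by `n` segments of rest
#' length `h`, each segment carrying an orthonormal material frame (stored as
#' a unit quaternion) and an active polymorphic state index.  Bead 1 sits at
#' the motor (origin); an anchored base frame, free to spin about the lab z
#' axis (the motor axis) by `baseAngle`, closes the proximal junction.
#'
#' @slot positions numeric matrix, `(n+1) x 3`, bead positions (um)
#' @slot quats numeric matrix, `n x 4`, unit quaternions `(w, x, y, z)` of
#'   the segment frames
#' @slot baseQuat unit quaternion of the anchored base frame at zero spin
#' @slot baseAngle accumulated base spin about the motor axis (rad)
#' @slot stateIndex integer vector, active polymorphic state per segment
#'   (1-based)
#' @slot h rest segment length (um)
#' @export
setClass("FilamentState",
  representation(positions = "matrix", quats = "matrix", baseQuat = "numeric",
                 baseAngle = "numeric", stateIndex = "integer", h = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@quats)
    if (nrow(object@positions) != n + 1 || ncol(object@positions) != 3)
      msg <- c(msg, "positions must be (n+1) x 3")
    if (ncol(object@quats) != 4) msg <- c(msg, "quats must be n x 4")
    if (length(object@stateIndex) != n)
      msg <- c(msg, "stateIndex must have one entry per segment")
    qn <- sqrt(rowSums(object@quats^2))
    if (any(abs(qn - 1) > 1e-6))
      msg <- c(msg, "frames not orthonormal (quaternion norms deviate from 1)")
    if (abs(sum(object@baseQuat^2) - 1) > 1e-6)
      msg <- c(msg, "baseQuat must be a unit quaternion")
    if (object@h <= 0) msg <- c(msg, "h must be > 0")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FilamentState", function(object) {
  n <- nrow(object@quats)
  cat(sprintf("FilamentState: %d segments, h = %.4g um, Lc = %.4g um\n",
              n, object@h, n * object@h))
  tip <- object@positions[n + 1, ]
  cat(sprintf("  free end at (%.3g, %.3g, %.3g) um; base angle %.3g rad\n",
              tip[1], tip[2], tip[3], object@baseAngle))
})

#' Motor drive
#'
#' @slot torque motor torque M (pN um), applied to the base frame about the
#'   lab z (motor) axis.  Positive torque drives the rotation sense that
#'   pulls the filament toward the motor plane (the screw-forming, CW sense);
#'   negative torque is the pushing (CCW) sense.
#' @export
setClass("MotorDrive", representation(torque = "numeric"),
  validity = function(object)
    if (is.finite(object@torque)) TRUE else "torque must be finite")

#' @rdname MotorDrive-class
#' @param torque motor torque (pN um)
#' @export
MotorDrive <- function(torque = 0) new("MotorDrive", torque = torque)

#' Integrator configuration
#'
#' Settings for the adaptive embedded Cash-Karp integration of the
#' overdamped equations of motion.
#'
#' @slot duration simulated time (s), default 0.060 (screw formation takes
#'   about 60 ms)
#' @slot relTol,absTol relative / absolute local error tolerances
#' @slot minStep,maxStep step-size bounds (s)
#' @slot snapshotInterval interval between recorded state snapshots (s)
#' @slot forceInterval sampling interval of the instantaneous axial force and
#'   base angle (s)
#' @slot polymorphic whether polymorphic state switching is active
#' @slot earlyExit stop as soon as the free end has stayed below `exitZ` for
#'   `exitHold` seconds (used by threshold searches; wrapped configurations
#'   do not recover)
#' @slot exitZ,exitHold early-exit criterion (um, s)
#' @slot strainAbort bond-strain level that aborts the run (relative), 1e-3
#' @export
setClass("IntegratorConfig",
  representation(duration = "numeric", relTol = "numeric", absTol = "numeric",
                 minStep = "numeric", maxStep = "numeric",
                 snapshotInterval = "numeric", forceInterval = "numeric",
                 polymorphic = "logical", earlyExit = "logical",
                 exitZ = "numeric", exitHold = "numeric",
                 strainAbort = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
    if (object@relTol <= 0 || object@absTol <= 0)
      msg <- c(msg, "tolerances must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname IntegratorConfig-class
#' @param duration simulated time (s)
#' @param relTol,absTol error tolerances
#' @param minStep,maxStep step bounds (s)
#' @param snapshotInterval,forceInterval output sampling intervals (s)
#' @param polymorphic enable polymorphic switching
#' @param earlyExit,exitZ,exitHold early stop once the free end has stayed
#'   below `exitZ` um for `exitHold` s
#' @param strainAbort bond-strain abort level
#' @export
IntegratorConfig <- function(duration = 0.060, relTol = 1e-6, absTol = 1e-9,
                             minStep = 1e-14, maxStep = 1e-5,
                             snapshotInterval = 1e-3, forceInterval = 5e-5,
                             polymorphic = TRUE, earlyExit = FALSE,
                             exitZ = -0.5, exitHold = 6e-3,
                             strainAbort = 1e-3) {
  new("IntegratorConfig", duration = duration, relTol = relTol,
      absTol = absTol, minStep = minStep, maxStep = maxStep,
      snapshotInterval = snapshotInterval, forceInterval = forceInterval,
      polymorphic = polymorphic, earlyExit = earlyExit, exitZ = exitZ,
      exitHold = exitHold, strainAbort = strainAbort)
}

#' Simulation trajectory record
#'
#' Time series produced by [simulateFilament()]: state snapshots, the
#' instantaneous axial propulsive force transmitted at the base, and the
#' accumulated base rotation.
#'
#' @slot times snapshot times (s), strictly increasing
#' @slot positions 3 x (n+1) x S array of bead positions (um)
#' @slot quats 4 x n x S array of frame quaternions
#' @slot stateIndex n x S matrix of active polymorphic states (1-based)
#' @slot baseAngle base rotation at snapshot times (rad)
#' @slot forceTimes,axialForce,forceBaseAngle fine-grained samples of time,
#'   axial force (pN) and base angle (rad)
#' @slot maxBondStrain largest relative bond-length deviation observed at any
#'   recorded snapshot
#' @slot config list of run parameters (n, h, torque, K used, ...)
#' @slot status integer: 0 completed, 1 early exit (persistent screw)
#' @slot message diagnostic message
#' @slot diagnostics list (accepted/rejected step counts, switches, ...)
#' @export
setClass("TrajectoryRecord",
  representation(times = "numeric", positions = "array", quats = "array",
                 stateIndex = "matrix", baseAngle = "numeric",
                 forceTimes = "numeric", axialForce = "numeric",
                 forceBaseAngle = "numeric", maxBondStrain = "numeric",
                 config = "list", status = "integer", message = "character",
                 diagnostics = "list"),
  validity = function(object) {
    if (is.unsorted(object@times, strictly = TRUE))
      "snapshot times must be strictly increasing" else TRUE
  })

setMethod("show", "TrajectoryRecord", function(object) {
  n <- dim(object@positions)[2] - 1
  cat(sprintf("TrajectoryRecord: %d snapshots over %.4g ms, %d segments\n",
              length(object@times), 1e3 * max(object@times), n))
  cat(sprintf("  torque %.3g pN um; base rotations %.3g; max bond strain %.3g%%\n",
              object@config$torque,
              utils::tail(object@baseAngle, 1) / (2 * pi),
              100 * object@maxBondStrain))
  cat(sprintf("  status: %s\n", object@message))
})

# ---------------------------------------------------------------------------
# Screw pipeline results
# ---------------------------------------------------------------------------

#' Screw-formation call for one simulation
#'
#' @slot screwFormed logical; `TRUE` when the free end ends below the motor
#'   plane (z < 0) and stays there for the final 10% of the run
#' @slot zEnd final axial coordinate of the free end (um; motor plane = 0)
#' @slot onsetTime time of the last crossing below the motor plane (s), or
#'   `NA` if no screw formed
#' @export
setClass("ScrewCall",
  representation(screwFormed = "logical", zEnd = "numeric",
                 onsetTime = "numeric"),
  validity = function(object) {
    if (isTRUE(object@screwFormed) && is.finite(object@zEnd) &&
        object@zEnd >= 0)
      "screwFormed implies zEnd < 0" else TRUE
  })

setMethod("show", "ScrewCall", function(object) {
  if (object@screwFormed)
    cat(sprintf("ScrewCall: screw formed (onset %.3g ms, z_end = %.3g um)\n",
                1e3 * object@onsetTime, object@zEnd))
  else
    cat(sprintf("ScrewCall: no screw (z_end = %.3g um)\n", object@zEnd))
})

#' Composition-torque stability diagram
#'
#' @slot fractions proximal-flagellin fraction grid (ascending)
#' @slot torques torque grid (pN um, ascending)
#' @slot order `"flaA-proximal"` or `"flaB-proximal"`
#' @slot grid data.frame with one row per (fraction, torque) cell:
#'   `fraction`, `torque`, `screw`, `zEnd`, `onset`
#' @export
setClass("StabilityDiagram",
  representation(fractions = "numeric", torques = "numeric",
                 order = "character", grid = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@fractions)) msg <- c(msg, "fractions must ascend")
    if (is.unsorted(object@torques)) msg <- c(msg, "torques must ascend")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "StabilityDiagram", function(object) {
  cat(sprintf("StabilityDiagram (%s): %d fractions x %d torques, %d screw cells\n",
              object@order, length(object@fractions), length(object@torques),
              sum(object@grid$screw, na.rm = TRUE)))
})

#' Force-torque efficiency fit
#'
#' Least-squares fit through the origin of the mean axial propulsive force F
#' against motor torque M over pre-screw torques: `F = betaEff * M`.  A
#' larger `betaEff` means more efficient conversion of torque into thrust.
#'
#' @slot betaEff slope (1/um)
#' @slot r2 coefficient of determination of the through-origin fit
#' @slot torques torques used (pN um, all pre-screw)
#' @slot forces mean axial forces (pN)
#' @export
setClass("ForceTorqueFit",
  representation(betaEff = "numeric", r2 = "numeric", torques = "numeric",
                 forces = "numeric"))

setMethod("show", "ForceTorqueFit", function(object) {
  cat(sprintf("ForceTorqueFit: betaEff = %.4g /um (R^2 = %.4f) over %d torques\n",
              object@betaEff, object@r2, length(object@torques)))
})

# ---------------------------------------------------------------------------
# Tracking classes
# ---------------------------------------------------------------------------

#' Holographic frame stack
#'
#' @slot data numeric array `ny x nx x nframes` of intensity images
#' @slot pixelPitch pixel size in the sample plane (um/px)
#' @slot frameRate acquisition rate (Hz)
#' @slot wavelength illumination wavelength in vacuum (um)
#' @slot medium refractive index of the medium
#' @export
setClass("FrameStack",
  representation(data = "array", pixelPitch = "numeric", frameRate = "numeric",
                 wavelength = "numeric", medium = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3) msg <- c(msg, "data must be ny x nx x T")
    if (object@frameRate <= 0) msg <- c(msg, "frameRate must be > 0")
    if (object@wavelength <= 0 || object@pixelPitch <= 0)
      msg <- c(msg, "wavelength and pixelPitch must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname FrameStack-class
#' @param data `ny x nx x T` array
#' @param pixelPitch um per pixel in the sample plane (default matches a
#'   1.4 mm field of view on 1024 px)
#' @param frameRate frames per second
#' @param wavelength illumination wavelength (um)
#' @param medium refractive index
#' @export
FrameStack <- function(data, pixelPitch = 1400 / 1024, frameRate = 50,
                       wavelength = 0.642, medium = 1.33) {
  new("FrameStack", data = data, pixelPitch = pixelPitch,
      frameRate = frameRate, wavelength = wavelength, medium = medium)
}

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FrameStack: %d x %d px, %d frames at %g Hz (%.3g um/px, lambda %.3g um)\n",
              d[1], d[2], d[3], object@frameRate, object@pixelPitch,
              object@wavelength))
})

#' Reconstructed holographic volume
#'
#' @slot field complex array `ny x nx x nz`, the refocused field with the
#'   axial carrier phase exp(i k z) removed
#' @slot zPlanes axial positions of the reconstruction planes (um)
#' @slot pixelPitch lateral pixel size (um/px)
#' @export
setClass("HoloVolume",
  representation(field = "array", zPlanes = "numeric", pixelPitch = "numeric"))

setMethod("show", "HoloVolume", function(object) {
  d <- dim(object@field)
  cat(sprintf("HoloVolume: %d x %d px x %d planes, z in [%.4g, %.4g] um\n",
              d[1], d[2], d[3], min(object@zPlanes), max(object@zPlanes)))
})

#' Smoothed 3D cell track
#'
#' Piecewise-cubic smoothing-spline representation of a linked track, with
#' instantaneous speed, unit swimming direction and angular speed evaluated
#' at the frame times.
#'
#' @slot t frame times (s)
#' @slot pos fitted positions, `n x 3` (um)
#' @slot vel velocities from the spline derivative, `n x 3` (um/s)
#' @slot speed instantaneous speed (um/s), `>= 0`
#' @slot dir unit direction vectors, `n x 3`
#' @slot angSpeed angular speed d(theta)/dt (degrees/s)
#' @slot trackId originating track id
#' @export
setClass("SmoothedTrack",
  representation(t = "numeric", pos = "matrix", vel = "matrix",
                 speed = "numeric", dir = "matrix", angSpeed = "numeric",
                 trackId = "integer"),
  validity = function(object) {
    if (any(object@speed < 0)) "speed must be non-negative" else TRUE
  })

setMethod("show", "SmoothedTrack", function(object) {
  cat(sprintf("SmoothedTrack #%d: %.3g s, mean speed %.3g um/s\n",
              object@trackId, diff(range(object@t)), mean(object@speed)))
})

#' Run-tumble motility summary
#'
#' Normalized histograms (relative counts summing to one) of run durations
#' P(t), instantaneous speeds P(v) and turning angles P(theta) pooled over
#' motile tracks.
#'
#' @slot runHist data.frame `mid`, `count`, `p` (bin midpoints in s)
#' @slot speedHist data.frame `mid`, `count`, `p` (um/s)
#' @slot angleHist data.frame `mid`, `count`, `p` (degrees)
#' @slot nTracks,nMotile,nEvents bookkeeping counts
#' @export
setClass("MotilitySummary",
  representation(runHist = "data.frame", speedHist = "data.frame",
                 angleHist = "data.frame", nTracks = "integer",
                 nMotile = "integer", nEvents = "integer"))

setMethod("show", "MotilitySummary", function(object) {
  cat(sprintf("MotilitySummary: %d/%d motile tracks, %d reorientation events\n",
              object@nMotile, object@nTracks, object@nEvents))
})

#' Run-tumble generator parameters
#'
#' Defaults emulate the acquisition conditions of the holographic tracking
#' experiments: 50 Hz sampling for 60 s with localization noise of 0.5 um
#' laterally and 1 um axially, a bimodal swimming-speed population and
#' Poisson reorientation events with a broad turning-angle law that includes
#' a near-reversal component.
#'
#' @slot speedMeans,speedSds,speedWeights two-component speed mixture (um/s)
#' @slot tumbleRate Poisson reorientation rate (1/s)
#' @slot angleBroadWeight weight of the broad turning-angle component (the
#'   remainder is a near-reversal Gaussian at 160 +- 15 degrees)
#' @slot rotDiff rotational diffusion of the heading (rad^2/s)
#' @slot transDiff translational diffusion (um^2/s)
#' @slot frameRate sampling rate (Hz)
#' @slot duration track duration (s)
#' @slot sigmaXY,sigmaZ localization noise (um)
#' @export
setClass("RunTumbleParams",
  representation(speedMeans = "numeric", speedSds = "numeric",
                 speedWeights = "numeric", tumbleRate = "numeric",
                 angleBroadWeight = "numeric", rotDiff = "numeric",
                 transDiff = "numeric", frameRate = "numeric",
                 duration = "numeric", sigmaXY = "numeric", sigmaZ = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(sum(object@speedWeights) - 1) > 1e-9)
      msg <- c(msg, "speedWeights must sum to 1")
    if (object@tumbleRate < 0 || object@rotDiff < 0 || object@transDiff < 0)
      msg <- c(msg, "rates and diffusivities must be >= 0")
    if (object@frameRate <= 0 || object@duration <= 0)
      msg <- c(msg, "frameRate and duration must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @rdname RunTumbleParams-class
#' @param speedMeans,speedSds,speedWeights speed mixture components (um/s)
#' @param tumbleRate reorientation rate (1/s)
#' @param angleBroadWeight weight of the broad angle component
#' @param rotDiff,transDiff rotational (rad^2/s) and translational (um^2/s)
#'   diffusion
#' @param frameRate sampling rate (Hz)
#' @param duration track length (s)
#' @param sigmaXY,sigmaZ localization noise (um)
#' @export
RunTumbleParams <- function(speedMeans = c(5, 60), speedSds = c(2, 8),
                            speedWeights = c(0.3, 0.7), tumbleRate = 0.5,
                            angleBroadWeight = 0.7, rotDiff = 0.05,
                            transDiff = 0.2, frameRate = 50, duration = 60,
                            sigmaXY = 0.5, sigmaZ = 1.0) {
  new("RunTumbleParams", speedMeans = speedMeans, speedSds = speedSds,
      speedWeights = speedWeights, tumbleRate = tumbleRate,
      angleBroadWeight = angleBroadWeight, rotDiff = rotDiff,
      transDiff = transDiff, frameRate = frameRate, duration = duration,
      sigmaXY = sigmaXY, sigmaZ = sigmaZ)
}

setMethod("show", "RunTumbleParams", function(object) {
  cat(sprintf("RunTumbleParams: %g Hz x %g s, tumble rate %g /s, speeds (%s) um/s\n",
              object@frameRate, object@duration, object@tumbleRate,
              paste(object@speedMeans, collapse = ", ")))
})
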