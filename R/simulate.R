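# Driven-filament simulation and trajectory-level measurements.

#' Simulate a motor-driven flagellar filament
#'
#' Integrates the overdamped dynamics of the discretized filament under a
#' fixed motor torque with an embedded Cash-Karp scheme: bead velocities
#' follow from the instantaneous balance of elastic forces against local
#' anisotropic (resistive-force-theory) drag, frames spin against their
#' rotational drag, the base bead is clamped at the origin and the base
#' frame rotates about the motor (z) axis under the applied torque.
#' Polymorphic state relabeling runs after every accepted step and frames
#' are re-orthonormalized.  The run is deterministic given its
#' configuration.
#'
#' When `elastic@K` is `NA` the stretching constant is calibrated
#' automatically for the requested torque; if the bond-length invariant
#' (0.1%) still trips, the run is retried once with a stiffer spring before
#' giving up.
#'
#' @param composition a [CompositionProfile-class]
#' @param motor a [MotorDrive-class] or a torque in pN um
#' @param elastic an [ElasticParams-class]
#' @param fluid a [FluidParams-class]
#' @param integrator an [IntegratorConfig-class]
#' @param nSegments number of segments (40 for the reference resolution)
#' @param initialState optional starting [FilamentState-class]; default is
#'   the piecewise equilibrium left-handed helix
#' @return a [TrajectoryRecord-class]
#' @export
simulateFilament <- function(composition, motor = MotorDrive(0),
                             elastic = ElasticParams(), fluid = FluidParams(),
                             integrator = IntegratorConfig(),
                             nSegments = 40L, initialState = NULL) {
  if (is.numeric(motor)) motor <- MotorDrive(motor)
  state <- if (is.null(initialState))
    buildInitialFilament(composition, elastic, nSegments) else initialState
  autoK <- is.na(elastic@K)
  K <- if (autoK) .calibrateK(motor@torque) else elastic@K
  for (attempt in 1:4) {
    cfg <- .engineConfig(state, composition, elastic, fluid,
                         torque = motor@torque, K = K)
    intg <- list(duration = integrator@duration, relTol = integrator@relTol,
                 absTol = integrator@absTol, dtInit = 1e-9,
                 minStep = integrator@minStep, maxStep = integrator@maxStep,
                 snapshotInterval = integrator@snapshotInterval,
                 forceInterval = integrator@forceInterval,
                 polymorphic = integrator@polymorphic,
                 earlyExit = integrator@earlyExit, exitZ = integrator@exitZ,
                 exitHold = integrator@exitHold,
                 strainAbort = integrator@strainAbort, maxSteps = 5e7)
    res <- .cpp_simulate(cfg, .stateList(state), intg)
    if (res$status != 3 || !autoK) break
    K <- 1.8 * K   # strain invariant tripped: stiffen the spring and retry
  }
  if (res$status == 2)
    stop("stiffness error: ", res$message, " at t = ", signif(res$finalTime, 4))
  if (res$status == 4)
    stop("step budget exhausted at t = ", signif(res$finalTime, 4),
         " s; the configuration is too stiff for the allotted integration")
  if (res$status == 3)
    stop("invariant breach: ", res$message,
         " (max bond strain ", signif(100 * res$maxBondStrain, 3), "%)")
  new("TrajectoryRecord",
      times = res$times, positions = res$positions, quats = res$quats,
      stateIndex = res$stateIndex + 1L, baseAngle = res$baseAngle,
      forceTimes = res$forceTimes, axialForce = res$axialForce,
      forceBaseAngle = res$forceBaseAngle, maxBondStrain = res$maxBondStrain,
      config = list(n = cfg$n, h = cfg$h, torque = motor@torque,
                    K = K, G = cfg$G, A = elastic@A, C = elastic@C,
                    rF = elastic@rF, eta = fluid@eta,
                    duration = integrator@duration,
                    Lc = composition@Lc, baseQuat = state@baseQuat,
                    flaAFraction = flaAFraction(composition)),
      status = as.integer(res$status), message = res$message,
      diagnostics = list(nAccept = res$nAccept, nReject = res$nReject,
                         nPolymorphicSwitches = res$nPolymorphicSwitches,
                         finalTime = res$finalTime))
}

#' Filament state at a snapshot
#'
#' @param record a [TrajectoryRecord-class]
#' @param i snapshot index (default: last)
#' @return a [FilamentState-class]
#' @export
snapshotState <- function(record, i = length(record@times)) {
  n <- dim(record@positions)[2] - 1L
  new("FilamentState",
      positions = t(record@positions[, , i]),
      quats = t(record@quats[, , i]),
      baseQuat = record@config$baseQuat %||% .defaultBaseQuat(record),
      baseAngle = record@baseAngle[i],
      stateIndex = as.integer(record@stateIndex[, i]),
      h = record@config$h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.defaultBaseQuat <- function(record) c(1, 0, 0, 0)

#' Axial position of the free end over time
#'
#' @param record a [TrajectoryRecord-class]
#' @return numeric vector, tip z (um) at the snapshot times
#' @export
tipZ <- function(record) {
  n <- dim(record@positions)[2]
  record@positions[3, n, ]
}

#' Mean axial propulsive force over whole rotation periods
#'
#' Averages the instantaneous axial force transmitted at the base over
#' exactly `periods` full base rotations (measured on the accumulated base
#' angle), ending at the last pre-screw sample, to remove the oscillation
#' tied to the motor's position relative to the filament axis.
#'
#' @param record a [TrajectoryRecord-class]
#' @param periods number of rotation periods to average over (default 10)
#' @return mean axial force (pN)
#' @export
meanAxialForce <- function(record, periods = 10) {
  t <- record@forceTimes
  f <- record@axialForce
  ang <- record@forceBaseAngle
  # end of usable window: screw onset if any, else end of run
  sc <- detectScrew(record)
  tEnd <- if (sc@screwFormed && is.finite(sc@onsetTime)) sc@onsetTime
          else max(t)
  keep <- t <= tEnd
  t <- t[keep]; f <- f[keep]; ang <- ang[keep]
  total <- abs(ang[length(ang)] - ang[1])
  if (record@config$torque == 0) return(mean(f[-seq_len(length(f) %/% 2)]))
  if (total < periods * 2 * pi)
    stop("insufficient-data error: fewer than ", periods,
         " base rotations before screw onset (", signif(total / (2 * pi), 3),
         " available)")
  aEnd <- ang[length(ang)]
  aStart <- aEnd - sign(aEnd - ang[1]) * periods * 2 * pi
  i0 <- max(which((ang - aStart) * sign(aEnd - ang[1]) <= 0))
  # trapezoidal time average over [t[i0], tEnd]
  tt <- t[i0:length(t)]; ff <- f[i0:length(f)]
  sum(diff(tt) * (ff[-1] + ff[-length(ff)]) / 2) / (tt[length(tt)] - tt[1])
}
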