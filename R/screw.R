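# Screw-formation classification, torque thresholds, stability diagrams and
# the force-torque efficiency fit.

#' Classify screw formation in a trajectory
#'
#' A simulation counts as screw formation when the filament's free end has
#' fallen below the motor plane (z < 0) and remains below it for the final
#' 10% of the run.  The persistence requirement rejects transient dips of
#' the tip during regular rotation.  Runs stopped early because the tip had
#' persistently settled below the exit depth are screw calls by
#' construction.
#'
#' @param record a [TrajectoryRecord-class]
#' @return a [ScrewCall-class]
#' @export
detectScrew <- function(record) {
  z <- tipZ(record)
  t <- record@times
  zEnd <- z[length(z)]
  if (record@status == 1L) {
    below <- z < 0
    onset <- t[.lastCrossing(below)]
    return(new("ScrewCall", screwFormed = TRUE, zEnd = zEnd,
               onsetTime = onset))
  }
  tailStart <- max(t) - 0.1 * record@config$duration
  inTail <- t >= tailStart
  formed <- all(z[inTail] < 0) && zEnd < 0
  if (!formed)
    return(new("ScrewCall", screwFormed = FALSE, zEnd = zEnd,
               onsetTime = NA_real_))
  below <- z < 0
  new("ScrewCall", screwFormed = TRUE, zEnd = zEnd,
      onsetTime = t[.lastCrossing(below)])
}

# index of the first snapshot of the final contiguous below-plane stretch
.lastCrossing <- function(below) {
  if (all(below)) return(1L)
  last <- length(below)
  i <- last
  while (i > 1 && below[i - 1]) i <- i - 1L
  i
}

# one screw-or-not simulation; early exit is safe for classification because
# wrapped configurations do not unwrap at fixed torque
.screwAt <- function(composition, torque, elastic, fluid, integrator,
                     nSegments, earlyExit = TRUE) {
  integ <- integrator
  integ@earlyExit <- earlyExit
  rec <- simulateFilament(composition, MotorDrive(torque), elastic, fluid,
                          integ, nSegments)
  detectScrew(rec)
}

#' Minimal screw-forming motor torque
#'
#' Scans `torqueGrid` upward and returns the smallest grid torque whose
#' fixed-torque simulation forms a screw within the simulated window,
#' refined by bisection between the bracketing grid points down to
#' `resolution`.  The scan stops at the first screw-forming grid point, so
#' only local monotonicity around the threshold is assumed; well above
#' threshold the indicator at a fixed time window need not be monotone
#' (strongly driven states can wrap later than moderately driven ones).
#'
#' @param composition a [CompositionProfile-class]
#' @param torqueGrid candidate torques (pN um), ascending, spanning sub- and
#'   super-threshold values
#' @param resolution bisection refinement target (pN um)
#' @param elastic,fluid,integrator,nSegments forwarded to
#'   [simulateFilament()]
#' @param earlyExit allow early termination of clearly wrapped runs
#' @param verbose print progress
#' @return threshold torque (pN um); `Inf` with attribute
#'   `stableOnGrid = TRUE` when no grid torque forms a screw
#' @export
torqueThreshold <- function(composition, torqueGrid = seq(0, 12, by = 2),
                            resolution = 0.25, elastic = ElasticParams(),
                            fluid = FluidParams(),
                            integrator = IntegratorConfig(), nSegments = 40L,
                            earlyExit = TRUE, verbose = FALSE) {
  torqueGrid <- sort(torqueGrid)
  probe <- function(M) {
    sc <- .screwAt(composition, M, elastic, fluid, integrator, nSegments,
                   earlyExit)
    if (verbose)
      message(sprintf("  M = %.3g pN um -> %s", M,
                      if (sc@screwFormed) "screw" else "stable"))
    sc@screwFormed
  }
  iFirst <- NA_integer_
  for (i in seq_along(torqueGrid)) {
    if (torqueGrid[i] == 0) next            # zero torque never screws
    if (probe(torqueGrid[i])) { iFirst <- i; break }
  }
  if (is.na(iFirst)) {
    out <- Inf
    attr(out, "stableOnGrid") <- TRUE
    return(out)
  }
  if (iFirst == 1L) {
    warning("screw forms already at the lowest grid torque")
    return(torqueGrid[1])
  }
  lo <- torqueGrid[iFirst - 1L]
  hi <- torqueGrid[iFirst]
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Composition-torque stability diagram
#'
#' Runs one simulation plus screw classification per (fraction, torque)
#' cell.  `order = "flaA-proximal"` sweeps the proximal-FlaA fraction
#' (wild-type-like ordering); `"flaB-proximal"` sweeps the proximal-FlaB
#' fraction of the reversed ordering.  Per-cell simulation failures are
#' recorded as `NA` rows rather than aborting the sweep.
#'
#' @param fractions proximal-flagellin fractions in `[0, 1]`, ascending
#' @param torques torque grid (pN um), ascending
#' @param order flagellin ordering along the filament
#' @param Lc contour length (um)
#' @param elastic,fluid,integrator,nSegments forwarded to
#'   [simulateFilament()]
#' @param earlyExit allow early termination of wrapped runs
#' @param verbose print progress
#' @return a [StabilityDiagram-class]
#' @export
stabilityDiagram <- function(fractions, torques,
                             order = c("flaA-proximal", "flaB-proximal"),
                             Lc = 6, elastic = ElasticParams(),
                             fluid = FluidParams(),
                             integrator = IntegratorConfig(),
                             nSegments = 40L, earlyExit = TRUE,
                             verbose = FALSE) {
  order <- match.arg(order)
  fractions <- sort(fractions); torques <- sort(torques)
  rows <- vector("list", length(fractions) * length(torques))
  r <- 0L
  for (fr in fractions) {
    flaAfr <- if (order == "flaA-proximal") fr else 1 - fr
    comp <- compositionProfile(flaAfr, Lc = Lc, order = order)
    for (M in torques) {
      r <- r + 1L
      cell <- tryCatch({
        sc <- .screwAt(comp, M, elastic, fluid, integrator, nSegments,
                       earlyExit)
        data.frame(fraction = fr, torque = M, screw = sc@screwFormed,
                   zEnd = sc@zEnd, onset = sc@onsetTime)
      }, error = function(e) {
        warning("cell (", fr, ", ", M, ") failed: ", conditionMessage(e))
        data.frame(fraction = fr, torque = M, screw = NA, zEnd = NA_real_,
                   onset = NA_real_)
      })
      rows[[r]] <- cell
      if (verbose)
        message(sprintf("fraction %.3g, M %.3g -> %s", fr, M,
                        if (isTRUE(cell$screw)) "screw" else "stable"))
    }
  }
  new("StabilityDiagram", fractions = fractions, torques = torques,
      order = order, grid = do.call(rbind, rows))
}

#' Force-torque efficiency (beta_eff) of a composition
#'
#' Simulates the listed torques, keeps pre-screw runs with at least the
#' required number of base rotations, and fits the mean axial force against
#' torque by least squares through the origin: `F = betaEff * M`.
#'
#' @param composition a [CompositionProfile-class]
#' @param torques at least three candidate torques (pN um)
#' @param periods rotation periods used by [meanAxialForce()]
#' @param elastic,fluid,integrator,nSegments forwarded to
#'   [simulateFilament()]
#' @return a [ForceTorqueFit-class]
#' @export
fitBetaEff <- function(composition, torques, periods = 10,
                       elastic = ElasticParams(), fluid = FluidParams(),
                       integrator = IntegratorConfig(), nSegments = 40L) {
  Ms <- numeric(); Fs <- numeric()
  for (M in torques) {
    rec <- simulateFilament(composition, MotorDrive(M), elastic, fluid,
                            integrator, nSegments)
    if (detectScrew(rec)@screwFormed) next
    f <- tryCatch(meanAxialForce(rec, periods), error = function(e) {
      warning("torque ", M, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(f)) next
    Fs <- c(Fs, f)
    Ms <- c(Ms, M)
  }
  if (length(Ms) < 3)
    stop("insufficient pre-screw torques for the force-torque fit (",
         length(Ms), " < 3)")
  beta <- sum(Fs * Ms) / sum(Ms^2)
  ss <- 1 - sum((Fs - beta * Ms)^2) / sum((Fs - mean(Fs))^2)
  new("ForceTorqueFit", betaEff = beta, r2 = ss, torques = Ms, forces = Fs)
}
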