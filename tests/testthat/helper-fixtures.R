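# Shared fixture builders for the test suite.  Everything is generated in
# code; simulations used by unit tests are deliberately small (few segments,
# few milliseconds) -- the acceptance suite runs the full-size conditions.

flaAGeom <- function() HelixGeometry(0.175, 1.18, "left")
flaBGeom <- function() HelixGeometry(0.315, 1.91, "left")

# a small, fast simulation for engine-level behavior checks
tinySim <- function(torque, frac = 0, n = 10, duration = 5e-3, ...) {
  simulateFilament(compositionProfile(frac), MotorDrive(torque),
                   integrator = IntegratorConfig(duration = duration, ...),
                   nSegments = n)
}

# randomly perturbed (but valid) filament state for gradient/energy tests
perturbedState <- function(state, posSd = 0.02, rotSd = 0.05, seed = 1) {
  set.seed(seed)
  n <- nrow(state@quats)
  state@positions <- state@positions +
    matrix(rnorm(3 * (n + 1), sd = posSd), ncol = 3)
  state@positions[1, ] <- 0
  for (i in seq_len(n)) {
    dq <- flamech:::.qexp(rnorm(3, sd = rotSd))
    state@quats[i, ] <- flamech:::.qmul(state@quats[i, ], dq)
  }
  state
}

# hand-built trajectory record with a prescribed tip-z time series
fakeRecord <- function(tipZSeries, duration = 0.06, torque = 5) {
  S <- length(tipZSeries)
  times <- seq(0, duration, length.out = S)
  n <- 4L
  pos <- array(0, c(3, n + 1, S))
  for (s in seq_len(S)) {
    pos[3, , s] <- seq(0, tipZSeries[s], length.out = n + 1)
  }
  quats <- array(rep(c(1, 0, 0, 0), n * S), c(4, n, S))
  new("TrajectoryRecord",
      times = times, positions = pos, quats = quats,
      stateIndex = matrix(1L, n, S), baseAngle = seq(0, 100, length.out = S),
      forceTimes = times, axialForce = rep(0, S),
      forceBaseAngle = seq(0, 100, length.out = S),
      maxBondStrain = 0, config = list(n = n, h = 1.5, torque = torque,
                                       duration = duration,
                                       baseQuat = c(1, 0, 0, 0)),
      status = 0L, message = "completed", diagnostics = list())
}

# straight constant-velocity track sampled at 50 Hz
straightTrack <- function(speed = 30, duration = 10, dir = c(1, 0, 0),
                          rate = 50, sigmaXY = 0, sigmaZ = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)
  d <- dir / sqrt(sum(dir^2))
  data.frame(trackId = 1L, t = t,
             x = speed * t * d[1] + rnorm(length(t), 0, sigmaXY),
             y = speed * t * d[2] + rnorm(length(t), 0, sigmaXY),
             z = speed * t * d[3] + rnorm(length(t), 0, sigmaZ))
}

# pure Brownian track
brownianTrack <- function(D = 0.2, duration = 10, rate = 50,
                          sigmaXY = 0.5, sigmaZ = 1, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration, by = 1 / rate)
  step <- sqrt(2 * D / rate)
  data.frame(trackId = 1L, t = t,
             x = cumsum(rnorm(length(t), 0, step)) + rnorm(length(t), 0, sigmaXY),
             y = cumsum(rnorm(length(t), 0, step)) + rnorm(length(t), 0, sigmaXY),
             z = cumsum(rnorm(length(t), 0, step)) + rnorm(length(t), 0, sigmaZ))
}
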