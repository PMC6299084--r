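# Screw classification and the composition/torque analysis pipeline.

test_that("screw calls follow the persistence rule on constructed records", {
  # tip stays high: no screw
  up <- fakeRecord(seq(4, 3.5, length.out = 61))
  expect_false(detectScrew(up)@screwFormed)

  # crosses below the plane at half time and stays: screw with that onset
  z <- c(seq(4, 0.5, length.out = 30), seq(-0.2, -1, length.out = 31))
  dn <- fakeRecord(z)
  sc <- detectScrew(dn)
  expect_true(sc@screwFormed)
  expect_lt(sc@zEnd, 0)
  expect_equal(sc@onsetTime, dn@times[31], tolerance = 1e-9)

  # transient dip that recovers before the final 10% is rejected
  zt <- c(seq(4, -0.5, length.out = 30), seq(-0.5, 2, length.out = 31))
  expect_false(detectScrew(fakeRecord(zt))@screwFormed)

  # a dip inside the final 10% of the run does not count either
  zl <- c(rep(3, 58), -0.1, -0.2, 0.4)
  expect_false(detectScrew(fakeRecord(zl))@screwFormed)
})

test_that("force-torque fit is linear through the origin on pre-screw runs", {
  comp <- compositionProfile(0)
  # torques well below the screw threshold, where the helix shape is close
  # to its rest geometry and thrust responds linearly
  fit <- fitBetaEff(comp, torques = c(1.5, 2, 3), periods = 4,
                    integrator = IntegratorConfig(duration = 0.08),
                    nSegments = 10)
  expect_gt(fit@betaEff, 0)
  expect_gte(fit@r2, 0.99)
  expect_identical(length(fit@torques), 3L)
  # exact synthetic linear data recover the exact slope (through-origin
  # least squares reduces to sum(FM)/sum(M^2))
  Ms <- c(1, 2, 3, 4); Fs <- 0.1 * Ms
  expect_equal(sum(Fs * Ms) / sum(Ms^2), 0.1, tolerance = 1e-14)
  expect_error(suppressWarnings(
    fitBetaEff(comp, torques = c(3, 4), periods = 5,
               integrator = IntegratorConfig(duration = 0.06),
               nSegments = 10)),
               "insufficient")
})

test_that("torque threshold via grid bisection matches an exhaustive scan", {
  # small filament, short window: cheap enough to scan exhaustively
  comp <- compositionProfile(0)
  grid <- c(0, 3, 6, 9)
  integ <- IntegratorConfig(duration = 0.02)
  scan <- vapply(grid, function(M)
    flamech:::.screwAt(comp, M, ElasticParams(), FluidParams(), integ,
                       10)@screwFormed, logical(1))
  thr <- torqueThreshold(comp, grid, resolution = 3,
                         integrator = integ, nSegments = 10)
  if (any(scan)) {
    expect_equal(thr, grid[which(scan)[1]])
    # indicator is monotone on the grid
    expect_true(all(diff(scan) >= 0))
  } else {
    expect_true(is.infinite(thr))
    expect_true(attr(thr, "stableOnGrid"))
  }
})

test_that("stability diagram covers the grid and zero torque never screws", {
  dg <- stabilityDiagram(fractions = c(0, 0.5, 1), torques = c(0, 2),
                         nSegments = 8,
                         integrator = IntegratorConfig(duration = 4e-3))
  expect_identical(nrow(dg@grid), 6L)
  expect_true(all(!dg@grid$screw[dg@grid$torque == 0]))
  expect_true(all(is.finite(dg@grid$zEnd)))
  # deterministic pipeline: identical configuration, identical diagram
  dg2 <- stabilityDiagram(fractions = c(0, 0.5, 1), torques = c(0, 2),
                          nSegments = 8,
                          integrator = IntegratorConfig(duration = 4e-3))
  expect_identical(dg@grid, dg2@grid)
})
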