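# Synthetic-data generators.

test_that("zero noise and zero tumbling gives an exact straight track", {
  p <- RunTumbleParams(speedMeans = c(30, 30), speedSds = c(0, 0),
                       speedWeights = c(0.5, 0.5), tumbleRate = 0,
                       rotDiff = 0, transDiff = 0, sigmaXY = 0, sigmaZ = 0,
                       duration = 5)
  gen <- genRunTumbleTracks(p, nTracks = 1, seed = 2)
  tr <- gen$tracks
  d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
  expect_equal(d, rep(30 / 50, nrow(tr) - 1), tolerance = 1e-10)
  # straightness: displacement equals path length
  disp <- sqrt((tr$x[nrow(tr)] - tr$x[1])^2 + (tr$y[nrow(tr)] - tr$y[1])^2 +
               (tr$z[nrow(tr)] - tr$z[1])^2)
  expect_equal(disp, 30 * 5, tolerance = 1e-8)
  expect_identical(nrow(gen$truth), 0L)
})

test_that("sampling cadence and duration match the acquisition defaults", {
  p <- RunTumbleParams()
  expect_equal(p@frameRate, 50)
  expect_equal(p@duration, 60)
  gen <- genRunTumbleTracks(RunTumbleParams(duration = 60), nTracks = 1,
                            seed = 3)
  tt <- gen$tracks$t
  expect_equal(diff(tt)[1], 1 / 50, tolerance = 1e-12)
  expect_equal(max(tt), 60, tolerance = 1e-9)
  expect_identical(nrow(gen$tracks), 3001L)
})

test_that("generation is deterministic per seed", {
  a <- genRunTumbleTracks(RunTumbleParams(duration = 10), 3, seed = 99)
  b <- genRunTumbleTracks(RunTumbleParams(duration = 10), 3, seed = 99)
  cc <- genRunTumbleTracks(RunTumbleParams(duration = 10), 3, seed = 100)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$tracks, cc$tracks))
})

test_that("generated run durations follow the exponential law", {
  p <- RunTumbleParams(tumbleRate = 0.5, duration = 40)
  gen <- genRunTumbleTracks(p, nTracks = 60, seed = 17)
  gaps <- unlist(lapply(split(gen$truth, gen$truth$trackId),
                        function(e) diff(sort(e$time))))
  expect_gt(length(gaps), 300)
  ks <- suppressWarnings(ks.test(gaps, pexp, rate = 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("turning angles stay in [0, 180] and include a reversal component", {
  gen <- genRunTumbleTracks(RunTumbleParams(tumbleRate = 1, duration = 30),
                            nTracks = 30, seed = 23)
  expect_true(all(gen$truth$angle >= 0 & gen$truth$angle <= 180))
  expect_gt(mean(gen$truth$angle > 140), 0.1)   # near-reversal component
})

test_that("point-hologram generator produces a unit-background stack", {
  stk <- genPointHologram(data.frame(frame = integer(), x = numeric(),
                                     y = numeric(), z = numeric()),
                          nPixels = 64, noise = 0, seed = 1)
  expect_equal(as.numeric(stk@data), rep(1, 64 * 64), tolerance = 1e-12)
  expect_equal(stk@wavelength, 0.642)
  stk2 <- genPointHologram(data.frame(frame = 1, x = 0, y = 0, z = 150),
                           nPixels = 64, noise = 0, seed = 1)
  expect_gt(diff(range(stk2@data)), 0.001)   # interference fringes present
})

test_that("strain fixtures carry the measured proximal fractions", {
  fx <- strainFixtures()
  expect_equal(flaAFraction(fx$FlaAB), 0.17)
  expect_equal(flaAFraction(fx$FlaAonly), 1)
  expect_equal(flaAFraction(fx$FlaBonly), 0)
  expect_equal(flaAFraction(fx$FlaAAB), 0.24)
  expect_equal(1 - flaAFraction(fx$FlaBA), 0.068)
  expect_equal(1 - flaAFraction(fx$FlaBBA), 0.081)
  # ordering: FlaAB has FlaA at the base, FlaBA has FlaB at the base
  expect_identical(fx$FlaAB@flagellins[[1]]@name, "FlaA")
  expect_identical(fx$FlaBA@flagellins[[1]]@name, "FlaB")
})
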