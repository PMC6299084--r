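# Track smoothing, motility classification, reorientation detection and
# the motility summary.

test_that("noiseless ballistic track: speed recovered essentially exactly", {
  tr <- straightTrack(speed = 30, duration = 10)
  sm <- smoothTrack(tr, sigmaXY = 0, sigmaZ = 0)
  inner <- 10:(length(sm@speed) - 10)
  expect_lt(max(abs(sm@speed[inner] - 30)), 0.1)
  # smoothing bias below 0.5%
  expect_lt(abs(mean(sm@speed[inner]) - 30) / 30, 0.005)
})

test_that("noisy straight track: mean speed within 5% of truth", {
  tr <- straightTrack(speed = 30, duration = 20, sigmaXY = 0.5, sigmaZ = 1,
                      seed = 4)
  sm <- smoothTrack(tr)
  expect_lt(abs(median(sm@speed) - 30) / 30, 0.05)
})

test_that("too-short tracks are skipped with a warning", {
  tr <- straightTrack(duration = 0.1)[1:5, ]
  expect_warning(out <- smoothTrack(tr), "short")
  expect_null(out)
})

test_that("smoothed Brownian track stays diffusive (log-log slope ~ 1)", {
  tr <- brownianTrack(D = 0.5, duration = 20, sigmaXY = 0, sigmaZ = 0,
                      seed = 2)
  sm <- smoothTrack(tr, sigmaXY = 0, sigmaZ = 0)
  m <- trackMSD(sm, seq(0.5, 4, by = 0.5))
  slope <- coef(lm(log(msd) ~ log(lag), data = m))[2]
  expect_gt(slope, 0.6)
  expect_lt(slope, 1.5)
})

test_that("motility classifier separates swimmers from Brownian tracks", {
  # ballistic noiseless: slope ~ 2, motile
  smB <- smoothTrack(straightTrack(speed = 30, duration = 10),
                     sigmaXY = 0, sigmaZ = 0)
  expect_true(isMotile(smB))
  # stationary noise-only track: non-motile
  still <- straightTrack(speed = 0, duration = 10, sigmaXY = 0.5,
                         sigmaZ = 1, seed = 6)
  expect_false(isMotile(smoothTrack(still)))
  # small-sample accuracy check (the acceptance suite runs the large one)
  set.seed(31)
  correct <- 0L
  for (i in 1:10) {
    swim <- smoothTrack(straightTrack(speed = 30, duration = 6,
                                      sigmaXY = 0.5, sigmaZ = 1))
    brown <- smoothTrack(brownianTrack(D = 0.2, duration = 6,
                                       seed = 100 + i))
    correct <- correct + isMotile(swim) + !isMotile(brown)
  }
  expect_gte(correct, 19L)
})

test_that("reorientation detection finds constructed turns and ignores
           sub-threshold wiggle", {
  # straight run: no events
  sm <- smoothTrack(straightTrack(speed = 30, duration = 10),
                    sigmaXY = 0, sigmaZ = 0)
  expect_identical(nrow(detectReorientations(sm)), 0L)

  # one 90-degree turn at t = 5 s
  t <- seq(0, 10, by = 0.02)
  turn <- data.frame(trackId = 1L, t = t,
                     x = 30 * pmin(t, 5), y = 30 * pmax(t - 5, 0), z = 0)
  smT <- smoothTrack(turn, sigmaXY = 0, sigmaZ = 0)
  ev <- detectReorientations(smT)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$time - 5), 0.1)
  expect_lt(abs(ev$angle - 90), 10)

  # angular speed never exceeding 4 deg/s stays below the 5 deg/s threshold
  slow <- data.frame(trackId = 1L, t = t,
                     x = 30 * cos(4 * pi / 180 * t),
                     y = 30 * sin(4 * pi / 180 * t), z = 5 * t)
  smS <- smoothTrack(slow, sigmaXY = 0, sigmaZ = 0)
  expect_lt(max(smS@angSpeed[20:480]), 5)
  evS <- detectReorientations(smS)
  expect_identical(nrow(evS), 0L)
})

test_that("raising the detection threshold never adds events", {
  set.seed(8)
  gen <- genRunTumbleTracks(RunTumbleParams(duration = 20), nTracks = 3,
                            seed = 8)
  for (tr in split(gen$tracks, gen$tracks$trackId)) {
    sm <- smoothTrack(tr)
    counts <- vapply(c(5, 10, 20, 40), function(th)
      nrow(detectReorientations(sm, threshold = th)), integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("run durations are inter-event intervals, censoring short lists", {
  expect_identical(runDurations(data.frame(time = 3)), numeric(0))
  expect_equal(runDurations(data.frame(time = c(2, 5, 9))), c(3, 4))
  expect_equal(runDurations(list(data.frame(time = c(1, 2)),
                                 data.frame(time = 7))), 1)
})

test_that("motility summary histograms are normalized with bounded support", {
  set.seed(14)
  gen <- genRunTumbleTracks(RunTumbleParams(duration = 20), nTracks = 6,
                            seed = 14)
  sm <- summarizeMotility(gen$tracks)
  expect_equal(sum(sm@runHist$p), 1, tolerance = 1e-12)
  expect_equal(sum(sm@speedHist$p), 1, tolerance = 1e-12)
  expect_equal(sum(sm@angleHist$p), 1, tolerance = 1e-12)
  expect_true(all(sm@angleHist$mid >= 0 & sm@angleHist$mid <= 180))
  expect_warning(summarizeMotility(list()), "no tracks")
})

test_that("bimodal speed mixture: both modes recovered", {
  p <- RunTumbleParams(speedMeans = c(5, 60), speedSds = c(0.5, 2),
                       speedWeights = c(0.5, 0.5), tumbleRate = 0.2,
                       duration = 15)
  gen <- genRunTumbleTracks(p, nTracks = 24, seed = 21)
  sm <- summarizeMotility(gen$tracks, motileOnly = FALSE)
  h <- sm@speedHist
  # a mode within one bin of each input population
  modeNear <- function(v) {
    w <- h$p[abs(h$mid - v) <= 3]
    length(w) && max(w) >= 0.8 * max(h$p[h$mid > v - 10 & h$mid < v + 10])
  }
  peaks <- h$mid[h$p > 0.05]
  expect_true(any(abs(peaks - 5) <= 3))
  expect_true(any(abs(peaks - 60) <= 4))
})
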