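# Holographic reconstruction and 3D localization.

test_that("median background normalization recovers static structure", {
  # constant stack -> background equals the constant, frames become 1
  stk <- FrameStack(array(3.7, c(16, 16, 5)))
  norm <- preprocessStack(stk)
  expect_equal(attr(norm@data, "background"), matrix(3.7, 16, 16))
  expect_equal(as.numeric(norm@data), rep(1, 16 * 16 * 5), tolerance = 1e-12)

  # static speckle + transient particle: background recovers the speckle
  set.seed(5)
  speckle <- matrix(runif(16 * 16, 0.5, 1.5), 16, 16)
  d <- array(rep(speckle, 7), c(16, 16, 7))
  d[8, 8, 4] <- d[8, 8, 4] + 2      # particle visits one pixel in one frame
  norm2 <- preprocessStack(FrameStack(d))
  expect_equal(attr(norm2@data, "background"), speckle, tolerance = 1e-12)
  resid <- norm2@data
  resid[8, 8, 4] <- NA
  expect_equal(as.numeric(resid[!is.na(resid)]),
               rep(1, sum(!is.na(resid))), tolerance = 1e-12)
  expect_gt(norm2@data[8, 8, 4], 2)

  # a single-frame impulse does not contaminate the median (a mean would)
  d3 <- array(1, c(8, 8, 9))
  d3[4, 4, 2] <- 100
  norm3 <- preprocessStack(FrameStack(d3))
  expect_equal(attr(norm3@data, "background")[4, 4], 1)
  expect_gt(mean(d3[4, 4, ]), 1 + 1)   # the mean is contaminated

  expect_warning(preprocessStack(FrameStack(array(0, c(4, 4, 3)))), "zero")
})

test_that("back-propagation at z = 0 without bandpass is the identity", {
  set.seed(9)
  fld <- matrix(complex(real = rnorm(32 * 32), imaginary = rnorm(32 * 32)),
                32, 32)
  vol <- rsBackpropagate(fld, 0, band = NULL, pixelPitch = 1.37)
  expect_equal(vol@field[, , 1], fld, tolerance = 1e-10)
})

test_that("forward then backward propagation restores a band-limited frame", {
  # smooth test field (band-limited so no evanescent loss)
  ax <- seq(-16, 15)
  g <- exp(-outer(ax^2, ax^2, "+") / 50) + 0i
  kg <- flamech:::.kzGrid(32, 32, 0.642, 1.37, 1.33)
  # forward propagation uses the conjugate kernel
  H <- exp(-1i * 120 * kg$dkz); H[!kg$prop] <- 0i
  fwd <- stats::fft(stats::fft(g) * H, inverse = TRUE) / (32 * 32)
  back <- rsBackpropagate(fwd, 120, pixelPitch = 1.37, band = NULL)
  expect_equal(Re(back@field[, , 1]), Re(g), tolerance = 1e-6)
})

test_that("bandpass removes pixel noise and slow gradients, keeps particles", {
  n <- 128
  ax <- seq_len(n)
  grid1px <- outer(ax, ax, function(i, j) 0.5 * (-1)^(i + j))  # Nyquist grid
  # smooth illumination profile varying on the ~100 px scale
  gradient <- outer(sin(2 * pi * ax / n), sin(2 * pi * ax / n)) * 0.5
  particle <- exp(-(outer((ax - 64)^2, (ax - 64)^2, "+")) / (2 * 5^2))
  filt <- function(img) {
    m <- flamech:::.bandMask(n, n, c(2, 30))
    Re(stats::fft(stats::fft(img) * m, inverse = TRUE)) / n^2
  }
  expect_lt(max(abs(filt(grid1px))), 0.02 * max(abs(grid1px)))
  expect_lt(max(abs(filt(gradient))), 0.05 * diff(range(gradient)))
  expect_gt(max(filt(particle)), 0.5 * max(particle))
})

test_that("a synthetic point scatterer is localized within 0.5 um lateral / 1 um axial", {
  pos <- data.frame(frame = 1, x = 30, y = -20, z = 200)
  stk <- genPointHologram(pos, nPixels = 256, noise = 0.003, seed = 7)
  vol <- rsBackpropagate(stk@data[, , 1], seq(100, 300, by = 5),
                         pixelPitch = stk@pixelPitch, medium = stk@medium)
  loc <- localizeCells(vol)
  expect_identical(nrow(loc), 1L)
  expect_lt(abs(loc$x - 30), 0.5)
  expect_lt(abs(loc$y + 20), 0.5)
  expect_lt(abs(loc$z - 200), 1.0)
})

test_that("a blank volume yields no detections", {
  set.seed(3)
  blank <- genPointHologram(data.frame(frame = integer(), x = numeric(),
                                       y = numeric(), z = numeric()),
                            nPixels = 64, noise = 0.003, seed = 3)
  vol <- rsBackpropagate(blank@data[, , 1], seq(100, 200, by = 10),
                         pixelPitch = blank@pixelPitch)
  loc <- localizeCells(vol, threshold = 0.05)
  expect_identical(nrow(loc), 0L)
})

test_that("two scatterers 50 um apart are recovered without merging", {
  pos <- data.frame(frame = 1, x = c(-100, -70), y = c(50, 10),
                    z = c(150, 180))
  stk <- genPointHologram(pos, nPixels = 256, noise = 0.003, seed = 8)
  vol <- rsBackpropagate(stk@data[, , 1], seq(100, 250, by = 5),
                         pixelPitch = stk@pixelPitch, medium = stk@medium)
  loc <- localizeCells(vol)
  expect_identical(nrow(loc), 2L)
  loc <- loc[order(loc$z), ]
  expect_lt(abs(loc$z[1] - 150), 2)
  expect_lt(abs(loc$z[2] - 180), 2)
  expect_lt(abs(loc$x[1] + 100), 1)
  expect_lt(abs(loc$x[2] + 70), 1)
  expect_lt(abs(loc$y[1] - 50), 1)
  expect_lt(abs(loc$y[2] - 10), 1)
})

test_that("greedy linking assembles, separates and bridges tracks", {
  # one detection per frame -> one full-length track
  det <- data.frame(frame = 1:20, x = (1:20) * 0.5, y = 0, z = 100)
  tr <- linkTracks(det)
  expect_identical(unique(tr$trackId), 1L)
  expect_identical(nrow(tr), 20L)

  # two well-separated particles -> two clean tracks
  det2 <- rbind(data.frame(frame = rep(1:15, each = 1), x = (1:15) * 0.4,
                           y = 0, z = 100),
                data.frame(frame = 1:15, x = 200 + (1:15) * 0.4, y = 50,
                           z = 300))
  tr2 <- linkTracks(det2)
  expect_identical(length(unique(tr2$trackId)), 2L)
  expect_true(all(table(tr2$trackId) == 15))

  # one-frame dropout bridged and flagged
  det3 <- data.frame(frame = c(1:5, 7:10), x = c(1:5, 7:10) * 0.5, y = 0,
                     z = 100)
  tr3 <- linkTracks(det3, maxGap = 1)
  expect_identical(length(unique(tr3$trackId)), 1L)
  expect_identical(nrow(tr3), 10L)
  expect_identical(tr3$interpolated, c(rep(FALSE, 5), TRUE, rep(FALSE, 4)))
  expect_equal(tr3$x[6], 3, tolerance = 1e-12)

  # without gap bridging the dropout splits the track
  tr4 <- linkTracks(det3, maxGap = 0)
  expect_identical(length(unique(tr4$trackId)), 2L)
})

test_that("linking is invariant to detection order within frames", {
  set.seed(12)
  det <- rbind(data.frame(frame = rep(1:10, each = 2),
                          x = c(rbind((1:10) * 0.5, 100 + (1:10) * 0.5)),
                          y = 0, z = 100))
  perm <- det[sample(nrow(det)), ]
  a <- linkTracks(det); b <- linkTracks(perm)
  key <- function(d) {
    d <- d[order(d$trackId, d$frame), ]
    split(d$x, d$trackId)
  }
  ka <- key(a); kb <- key(b)
  expect_identical(length(ka), length(kb))
  # same set of track position series regardless of input order
  expect_setequal(vapply(ka, paste, character(1), collapse = ","),
                  vapply(kb, paste, character(1), collapse = ","))
})
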