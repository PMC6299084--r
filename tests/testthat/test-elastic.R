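# Filament construction, strains, elastic energy, forces and polymorphic
# state selection.

test_that("constructed filament lies on the prescribed equilibrium helix", {
  comp <- compositionProfile(0)   # pure FlaB
  st <- buildInitialFilament(comp, nSegments = 40)
  fit <- helixMetrics(st@positions)
  expect_equal(fit$radius, 0.315, tolerance = 0.01)
  expect_equal(fit$pitch, 1.91, tolerance = 0.01)
  expect_identical(fit$handedness, "left")
  # bond lengths all exactly h
  bl <- sqrt(rowSums((st@positions[-1, ] - st@positions[-41, ])^2))
  expect_equal(bl, rep(st@h, 40), tolerance = 1e-12)
  expect_equal(st@h * 40, comp@Lc)
})

test_that("any single-flagellin construction is left-handed", {
  for (frac in c(0, 1)) {
    st <- buildInitialFilament(compositionProfile(frac), nSegments = 30)
    expect_identical(helixMetrics(st@positions)$handedness, "left")
  }
})

test_that("composite profile assigns proximal segments to FlaA", {
  comp <- compositionProfile(0.2)   # proximal 20% FlaA
  tab <- flamech:::.segmentTable(comp, 40)
  expect_identical(tab$names[1:8], rep("FlaA", 8))
  expect_identical(tab$names[9:40], rep("FlaB", 32))
  expect_equal(flaAFraction(comp), 0.2)
  # reversed order
  compB <- compositionProfile(1 - 0.068, order = "flaB-proximal")
  tabB <- flamech:::.segmentTable(compB, 40)
  expect_identical(tabB$names[1:2], c("FlaB", "FlaB"))
  expect_identical(tabB$names[40], "FlaA")
})

test_that("equilibrium strains equal the rest strain of each segment", {
  comp <- compositionProfile(0.25)
  st <- buildInitialFilament(comp, nSegments = 24)
  S <- segmentStrains(st)
  tab <- flamech:::.segmentTable(comp, 24)
  for (i in 1:24)
    expect_equal(S[, i], tab$rest[, 1, i], tolerance = 1e-9)
})

test_that("a pure twist between frames yields strain (0, 0, phi/h)", {
  comp <- compositionProfile(0)
  st <- buildInitialFilament(comp, nSegments = 8)
  phi <- 0.3
  i <- 5
  # make frame i differ from frame i-1 by a pure rotation phi about e3
  st@quats[i, ] <- flamech:::.qmul(st@quats[i - 1, ],
                                   flamech:::.qexp(c(0, 0, phi)))
  S <- segmentStrains(st)
  expect_equal(S[, i], c(0, 0, phi / st@h), tolerance = 1e-10)
})

test_that("segment strains reject corrupted frames", {
  st <- buildInitialFilament(compositionProfile(0), nSegments = 8)
  st@quats[3, ] <- st@quats[3, ] * 1.5
  expect_error(segmentStrains(st), "orthonormal")
})

test_that("elastic energy vanishes at rest and matches the straight-rod closed form", {
  comp <- compositionProfile(0)
  st <- buildInitialFilament(comp, nSegments = 40)
  e <- elasticEnergy(st, comp)
  expect_lt(sum(abs(e)), 1e-9)

  # straight untwisted rod with FlaA rest strain:
  # F_K = (Lc/2) (A kappa0^2 + C tau0^2) ~ 159.3 pN um
  compA <- compositionProfile(1)
  stA <- buildInitialFilament(compA, nSegments = 40)
  straight <- frameIntegrateHelix(c(0, 0, 0), h = stA@h, n = 40,
                                  q0 = c(1, 0, 0, 0))
  stA@positions <- straight$positions
  stA@quats <- straight$quats
  stA@baseQuat <- c(1, 0, 0, 0)
  eA <- elasticEnergy(stA, compA)
  om0 <- helixToStrain(flaAGeom())
  closed <- 6 / 2 * (3.5 * om0[1]^2 + 3.5 * om0[3]^2)
  expect_equal(closed, 159.3, tolerance = 1e-3)
  # the base junction models the soft hook, so one of the 40 junctions
  # deviates from the interior quadratic form (about 1% of the total)
  expect_equal(eA[["bendTwist"]], closed, tolerance = 0.02)
  expect_lt(eA[["stretch"]], 1e-9)
})

test_that("elastic energy is quadratic in small deviations", {
  comp <- compositionProfile(0)
  st <- buildInitialFilament(comp, nSegments = 16)
  base <- st
  dpos <- matrix(sin(1:51), ncol = 3) * 0.02
  dpos[1, ] <- 0
  e1 <- local({
    s <- base; s@positions <- s@positions + 0.1 * dpos
    sum(elasticEnergy(s, comp))
  })
  e2 <- local({
    s <- base; s@positions <- s@positions + 0.05 * dpos
    sum(elasticEnergy(s, comp))
  })
  expect_equal(e1 / e2, 4, tolerance = 0.01)
})

test_that("elastic forces are the exact gradient of the energy", {
  comp <- compositionProfile(0.3)
  st <- perturbedState(buildInitialFilament(comp, nSegments = 12), seed = 3)
  ef <- elasticForces(st, comp)
  # position gradient (central differences)
  fd <- flamech:::.fdForces(st, comp, ElasticParams(), beads = c(1, 2, 7, 13))
  expect_equal(fd, ef$forces[c(1, 2, 7, 13), ], tolerance = 1e-6)
  # frame-rotation gradient
  eps <- 1e-6
  for (i in c(1, 6, 12)) {
    fdt <- numeric(3)
    for (k in 1:3) {
      ax <- numeric(3); ax[k] <- eps
      sp <- st; sp@quats[i, ] <- flamech:::.qmul(st@quats[i, ],
                                                 flamech:::.qexp(ax))
      sm <- st; sm@quats[i, ] <- flamech:::.qmul(st@quats[i, ],
                                                 flamech:::.qexp(-ax))
      fdt[k] <- -(sum(elasticEnergy(sp, comp)) -
                  sum(elasticEnergy(sm, comp))) / (2 * eps)
    }
    expect_equal(fdt, ef$torques[i, ], tolerance = 1e-5 * max(1, max(abs(fdt))))
  }
})

test_that("internal forces and torques balance on arbitrary states", {
  comp <- compositionProfile(0.5)
  for (seed in 1:3) {
    st <- perturbedState(buildInitialFilament(comp, nSegments = 10),
                         seed = seed)
    ef <- elasticForces(st, comp)
    expect_lt(max(abs(colSums(ef$forces))), 1e-9)
    # total torque about the origin including the base reaction
    tw <- ef$baseTorque
    fr <- frames(st)
    for (i in 1:10) tw <- tw + fr[, , i] %*% ef$torques[i, ]
    for (b in 1:11) {
      r <- st@positions[b, ]; f <- ef$forces[b, ]
      tw <- tw + c(r[2] * f[3] - r[3] * f[2],
                   r[3] * f[1] - r[1] * f[3],
                   r[1] * f[2] - r[2] * f[1])
    }
    expect_lt(max(abs(tw)), 1e-8)
  }
})

test_that("forces vanish at equilibrium", {
  comp <- compositionProfile(0.2)
  st <- buildInitialFilament(comp, nSegments = 20)
  ef <- elasticForces(st, comp)
  expect_lt(max(abs(ef$forces)), 1e-8)
  expect_lt(max(abs(ef$torques)), 1e-8)
})

test_that("polymorphic selection: FlaA stays, strained FlaB switches, ties keep", {
  # FlaA segments always index 1 (single state)
  compA <- compositionProfile(1)
  stA <- perturbedState(buildInitialFilament(compA, nSegments = 8),
                        posSd = 0.1, rotSd = 0.3)
  expect_identical(selectPolymorphicStates(stA, compA)@stateIndex,
                   rep(1L, 8))

  # a FlaB filament strained exactly onto the curly rest state switches
  # (16 segments keep the per-junction rotation below pi)
  comp <- compositionProfile(0)
  curly <- helixToStrain(HelixGeometry(0.14, 1.0, "right"))
  hx <- frameIntegrateHelix(curly, h = 6 / 16, n = 16)
  st <- buildInitialFilament(comp, nSegments = 16)
  st@positions <- hx$positions
  st@quats <- hx$quats
  st@baseQuat <- hx$q0
  sel <- selectPolymorphicStates(st, comp)
  # interior segments relax to the curly basin (segment 1 adjoins the hook
  # junction and is exempt from relabeling)
  expect_identical(sel@stateIndex[2:16], rep(2L, 15))

  # exact energy tie keeps the current index
  om0 <- helixToStrain(flaBGeom())
  mid <- (om0 + curly) / 2
  hxM <- frameIntegrateHelix(mid, h = 6 / 16, n = 16)
  stM <- buildInitialFilament(comp, nSegments = 16)
  stM@positions <- hxM$positions
  stM@quats <- hxM$quats
  stM@baseQuat <- hxM$q0
  selM <- selectPolymorphicStates(stM, comp)
  expect_identical(selM@stateIndex, rep(1L, 16))
})

test_that("polymorphic selection never increases the elastic energy", {
  comp <- compositionProfile(0)
  for (seed in 1:4) {
    st <- perturbedState(buildInitialFilament(comp, nSegments = 10),
                         posSd = 0.15, rotSd = 0.6, seed = seed)
    e0 <- sum(elasticEnergy(st, comp))
    sel <- selectPolymorphicStates(st, comp)
    e1 <- sum(elasticEnergy(sel, comp))
    expect_lte(e1, e0 + 1e-9)
  }
})
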