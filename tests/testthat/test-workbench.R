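# Configuration round-tripping and the command-line style entry point.

test_that("run configurations round-trip losslessly", {
  cfg <- list("sim.torque" = 4.25, "sim.fractions" = c(0, 0.17, 0.24),
              "io.out" = "runs/a", "flags.polymorphic" = TRUE,
              "seed" = 7L)
  path <- tempfile()
  writeRunConfig(cfg, path)
  back <- readRunConfig(path)
  expect_equal(back[["sim.torque"]], 4.25)
  expect_equal(back[["sim.fractions"]], c(0, 0.17, 0.24))
  expect_identical(back[["io.out"]], "runs/a")
  expect_identical(back[["flags.polymorphic"]], TRUE)
  # hash is stable under key reordering and changes with values
  expect_identical(configHash(cfg), configHash(rev(cfg)))
  cfg2 <- cfg; cfg2[["sim.torque"]] <- 4.5
  expect_false(identical(configHash(cfg), configHash(cfg2)))
})

test_that("filament states round-trip through CSV", {
  st <- buildInitialFilament(compositionProfile(0.3), nSegments = 12)
  st@stateIndex[5] <- 2L
  path <- tempfile(fileext = ".csv")
  writeFilamentState(st, path)
  back <- readFilamentState(path)
  expect_equal(back@positions, st@positions, tolerance = 1e-14)
  expect_equal(back@quats, st@quats, tolerance = 1e-14)
  expect_identical(back@stateIndex, st@stateIndex)
  expect_equal(back@h, st@h)
})

test_that("synth subcommand is deterministic per seed", {
  d1 <- tempfile(); d2 <- tempfile()
  args <- function(out) c("synth", "--seed", "1", "--n-tracks", "2",
                          "--duration", "5", "--out", out)
  expect_identical(runCLI(args(d1)), 0L)
  expect_identical(runCLI(args(d2)), 0L)
  expect_identical(unname(tools::md5sum(file.path(d1, "tracks.csv"))),
                   unname(tools::md5sum(file.path(d2, "tracks.csv"))))
  # manifest carries seed and config hash
  man <- readRunConfig(file.path(d1, "manifest.txt"))
  expect_equal(man$seed, 1)
  expect_true(nzchar(man$config.hash))
  # a different seed changes the output
  d3 <- tempfile()
  runCLI(c("synth", "--seed", "2", "--n-tracks", "2", "--duration", "5",
           "--out", d3))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "tracks.csv"))),
                         unname(tools::md5sum(file.path(d3, "tracks.csv")))))
})

test_that("sweep subcommand writes the expected grid", {
  out <- tempfile()
  st <- runCLI(c("sweep", "--fractions", "0:1:0.5", "--torques", "0:2:1",
                 "--segments", "8", "--duration", "0.004", "--out", out))
  expect_identical(st, 0L)
  dg <- read.csv(file.path(out, "diagram.csv"))
  expect_identical(nrow(dg), 9L)
  expect_true(all(c("fraction", "torque", "screw", "zEnd", "onset") %in%
                  names(dg)))
})

test_that("missing required keys exit with status 2 naming the key", {
  expect_message(st <- runCLI(c("synth")), "out")
  expect_identical(st, 2L)
  expect_message(st2 <- runCLI(c("sweep", "--out", tempfile())), "fractions")
  expect_identical(st2, 2L)
  expect_identical(suppressMessages(runCLI(c("unknown-cmd"))), 2L)
  expect_identical(suppressMessages(runCLI(character())), 2L)
})

test_that("simulate subcommand writes state, trajectory and invariants", {
  out <- tempfile()
  st <- runCLI(c("simulate", "--torque", "1", "--segments", "8",
                 "--duration", "0.003", "--out", out))
  expect_identical(st, 0L)
  expect_true(file.exists(file.path(out, "final_state.csv")))
  traj <- read.csv(file.path(out, "trajectory.csv"))
  expect_true(all(c("t", "tipZ", "baseAngle") %in% names(traj)))
  man <- readRunConfig(file.path(out, "manifest.txt"))
  expect_true(man$invariant.bondStrainWithinLimit)
})
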