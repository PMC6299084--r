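# Command-line style entry point binding the stages into reproducible runs.

#' Run a pipeline stage from argument-vector form
#'
#' Dispatches the subcommands `simulate`, `sweep`, `analyze-tracks`,
#' `reconstruct` and `synth` with `--key value` arguments, writes the stage
#' outputs plus a manifest (configuration, seed, package version, config
#' hash and invariant checks) into the output directory, and returns an
#' exit status: 0 on success, 2 on configuration errors.  Identical
#' configuration and seed produce identical outputs.
#'
#' A thin executable wrapper suitable for `Rscript` ships in
#' `system.file("scripts", "flamech-cli.R", package = "flamech")`.
#'
#' @param args character vector, e.g.
#'   `c("simulate", "--torque", "4", "--flaA-fraction", "0.17", "--out", "run1")`
#' @return integer exit status, invisibly
#' @export
runCLI <- function(args) {
  if (!length(args)) {
    message("usage: flamech <simulate|sweep|analyze-tracks|reconstruct|synth> ",
            "[--key value ...]")
    return(invisible(2L))
  }
  sub <- args[1]
  opts <- .parseArgs(args[-1])
  if (is.character(opts)) { message(opts); return(invisible(2L)) }
  handler <- switch(sub,
    "simulate" = .cliSimulate, "sweep" = .cliSweep,
    "analyze-tracks" = .cliAnalyze, "reconstruct" = .cliReconstruct,
    "synth" = .cliSynth, NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub)
    return(invisible(2L))
  }
  status <- tryCatch(handler(opts), error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("missing required", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}

.parseArgs <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      return(paste("unexpected argument:", a))
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      return(paste("missing value for --", key))
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.req <- function(opts, key) {
  if (is.null(opts[[key]]))
    stop("missing required config key: --", key, call. = FALSE)
  opts[[key]]
}

.num <- function(opts, key, default = NULL) {
  v <- opts[[key]]
  if (is.null(v)) return(default)
  as.numeric(v)
}

.seedFrom <- function(opts) {
  s <- .num(opts, "seed", 1)
  set.seed(as.integer(s))
  as.integer(s)
}

.writeManifest <- function(dir, stage, config, seed, invariants = list()) {
  config$stage <- stage
  config$seed <- seed
  config$package.version <- as.character(utils::packageVersion("flamech"))
  config$config.hash <- configHash(config[setdiff(names(config),
                                                  "config.hash")])
  for (nm in names(invariants))
    config[[paste0("invariant.", nm)]] <- invariants[[nm]]
  writeRunConfig(config, file.path(dir, "manifest.txt"))
}

.outDir <- function(opts) {
  out <- .req(opts, "out")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  out
}

.cliSimulate <- function(opts) {
  out <- .outDir(opts)
  torque <- as.numeric(.req(opts, "torque"))
  frac <- .num(opts, "flaA-fraction", 0)
  n <- as.integer(.num(opts, "segments", 40))
  dur <- .num(opts, "duration", 0.06)
  eta <- .num(opts, "eta", 1e-3)
  comp <- compositionProfile(frac)
  rec <- simulateFilament(comp, MotorDrive(torque),
                          fluid = FluidParams(eta),
                          integrator = IntegratorConfig(duration = dur),
                          nSegments = n)
  sc <- detectScrew(rec)
  writeFilamentState(snapshotState(rec), file.path(out, "final_state.csv"))
  write.csv(data.frame(t = rec@times, tipZ = tipZ(rec),
                       baseAngle = rec@baseAngle),
            file.path(out, "trajectory.csv"), row.names = FALSE)
  write.csv(data.frame(t = rec@forceTimes, axialForce = rec@axialForce,
                       baseAngle = rec@forceBaseAngle),
            file.path(out, "axial_force.csv"), row.names = FALSE)
  .writeManifest(out, "simulate",
                 list(torque = torque, flaA.fraction = frac, segments = n,
                      duration = dur, eta = eta),
                 seed = NA,
                 invariants = list(
                   maxBondStrainPct = 100 * rec@maxBondStrain,
                   bondStrainWithinLimit = rec@maxBondStrain <= 1e-3,
                   screwFormed = sc@screwFormed))
  0L
}

.cliSweep <- function(opts) {
  out <- .outDir(opts)
  fracs <- .parseRange(.req(opts, "fractions"))
  torques <- .parseRange(.req(opts, "torques"))
  ord <- if (identical(opts[["order"]], "flaB-proximal"))
    "flaB-proximal" else "flaA-proximal"
  n <- as.integer(.num(opts, "segments", 40))
  dur <- .num(opts, "duration", 0.06)
  dg <- stabilityDiagram(fracs, torques, order = ord, nSegments = n,
                         integrator = IntegratorConfig(duration = dur))
  writeStabilityDiagram(dg, file.path(out, "diagram.csv"))
  .writeManifest(out, "sweep",
                 list(fractions = fracs, torques = torques, order = ord,
                      segments = n, duration = dur),
                 seed = NA,
                 invariants = list(cells = nrow(dg@grid),
                                   failures = sum(is.na(dg@grid$screw))))
  0L
}

# "a:b:step" or comma list
.parseRange <- function(s) {
  if (grepl(":", s)) {
    p <- as.numeric(strsplit(s, ":")[[1]])
    if (length(p) != 3 || any(is.na(p)))
      stop("range must be start:end:step, got ", s, call. = FALSE)
    seq(p[1], p[2], by = p[3])
  } else as.numeric(strsplit(s, ",")[[1]])
}

.cliAnalyze <- function(opts) {
  inPath <- .req(opts, "in")
  out <- .outDir(opts)
  tracks <- readTracks(inPath)
  sm <- summarizeMotility(tracks,
                          sigmaXY = .num(opts, "sigma-xy", 0.5),
                          sigmaZ = .num(opts, "sigma-z", 1.0))
  write.csv(sm@runHist, file.path(out, "run_durations.csv"), row.names = FALSE)
  write.csv(sm@speedHist, file.path(out, "speeds.csv"), row.names = FALSE)
  write.csv(sm@angleHist, file.path(out, "turning_angles.csv"),
            row.names = FALSE)
  .writeManifest(out, "analyze-tracks",
                 list(input = inPath), seed = NA,
                 invariants = list(nTracks = sm@nTracks, nMotile = sm@nMotile,
                                   nEvents = sm@nEvents))
  0L
}

.cliReconstruct <- function(opts) {
  inPath <- .req(opts, "in")
  out <- .outDir(opts)
  stack <- FrameStack(readRDSorCSVStack(inPath))
  norm <- preprocessStack(stack)
  zP <- .parseRange(.num2str(opts[["z"]], "5:500:5"))
  locs <- list()
  for (fr in seq_len(dim(norm@data)[3])) {
    vol <- rsBackpropagate(norm@data[, , fr], zP,
                           wavelength = norm@wavelength,
                           pixelPitch = norm@pixelPitch,
                           medium = norm@medium)
    lc <- localizeCells(vol)
    if (nrow(lc)) lc$frame <- fr
    locs[[fr]] <- lc
  }
  locs <- do.call(rbind, locs[vapply(locs, nrow, integer(1)) > 0])
  tracks <- linkTracks(locs, frameRate = norm@frameRate)
  writeTracks(tracks, file.path(out, "tracks.csv"))
  .writeManifest(out, "reconstruct", list(input = inPath), seed = NA,
                 invariants = list(nDetections = nrow(locs),
                                   nTracks = length(unique(tracks$trackId))))
  0L
}

.num2str <- function(v, default) if (is.null(v)) default else v

# frame stacks travel as plain CSV of long-format pixels (frame,row,col,value)
readRDSorCSVStack <- function(path) {
  df <- read.csv(path)
  ny <- max(df$row); nx <- max(df$col); nt <- max(df$frame)
  a <- array(0, c(ny, nx, nt))
  a[cbind(df$row, df$col, df$frame)] <- df$value
  a
}

.cliSynth <- function(opts) {
  out <- .outDir(opts)
  seed <- .seedFrom(opts)
  nTracks <- as.integer(.num(opts, "n-tracks", 5))
  params <- RunTumbleParams(
    tumbleRate = .num(opts, "tumble-rate", 0.5),
    duration = .num(opts, "duration", 60))
  gen <- genRunTumbleTracks(params, nTracks, seed = seed)
  writeTracks(gen$tracks, file.path(out, "tracks.csv"))
  write.csv(gen$truth, file.path(out, "events_truth.csv"), row.names = FALSE)
  .writeManifest(out, "synth",
                 list(n.tracks = nTracks, tumble.rate = params@tumbleRate,
                      duration = params@duration),
                 seed = seed,
                 invariants = list(nEvents = nrow(gen$truth)))
  0L
}
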