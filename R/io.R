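# CSV interchange for tracks, filament states and stability diagrams, and
# the flat dotted-key run-configuration format.

#' Read / write track tables
#'
#' Tracks travel as plain CSV with columns `trackId`, `t`, `x`, `y`, `z`
#' (and any extras preserved).
#'
#' @param tracks data.frame of tracks
#' @param path file path
#' @return `readTracks` returns the data.frame; `writeTracks` returns
#'   `path` invisibly
#' @export
writeTracks <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
  read.csv(path)
}

#' Serialize a filament state to CSV
#'
#' One row per bead: index, position, and (for rows 1..n) the frame
#' quaternion and active polymorphic state of the segment that starts at
#' that bead.
#'
#' @param state a [FilamentState-class]
#' @param path file path
#' @export
writeFilamentState <- function(state, path) {
  n <- nrow(state@quats)
  df <- data.frame(bead = seq_len(n + 1) - 1L,
                   x = state@positions[, 1], y = state@positions[, 2],
                   z = state@positions[, 3],
                   qw = c(state@quats[, 1], NA), qx = c(state@quats[, 2], NA),
                   qy = c(state@quats[, 3], NA), qz = c(state@quats[, 4], NA),
                   stateIndex = c(state@stateIndex, NA))
  attrLine <- sprintf("# h=%.17g baseAngle=%.17g baseQuat=%.17g,%.17g,%.17g,%.17g",
                      state@h, state@baseAngle, state@baseQuat[1],
                      state@baseQuat[2], state@baseQuat[3], state@baseQuat[4])
  con <- file(path, "w")
  writeLines(attrLine, con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeFilamentState
#' @export
readFilamentState <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-zA-Z]+=[-0-9.,e+]+", hdr))[[1]]
  meta <- list()
  for (s in kv) {
    p <- strsplit(s, "=")[[1]]
    meta[[p[1]]] <- as.numeric(strsplit(p[2], ",")[[1]])
  }
  df <- read.csv(path, skip = 1)
  n <- nrow(df) - 1L
  new("FilamentState",
      positions = unname(as.matrix(df[, c("x", "y", "z")])),
      quats = unname(as.matrix(df[seq_len(n), c("qw", "qx", "qy", "qz")])),
      baseQuat = meta$baseQuat, baseAngle = meta$baseAngle,
      stateIndex = as.integer(df$stateIndex[seq_len(n)]), h = meta$h)
}

#' Write a stability diagram as a CSV grid
#'
#' @param diagram a [StabilityDiagram-class]
#' @param path file path
#' @export
writeStabilityDiagram <- function(diagram, path) {
  write.csv(diagram@grid, path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# flat dotted-key configuration format
# ---------------------------------------------------------------------------

#' Read / write run configurations
#'
#' Flat structured text, one `dotted.key = value` per line; numeric and
#' logical values are restored on reading, so a configuration round-trips
#' losslessly.  Lines starting with `#` are comments.
#'
#' @param config named list (names may contain dots)
#' @param path file path
#' @export
writeRunConfig <- function(config, path) {
  keys <- sort(names(config))
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = ",")
    else if (is.logical(v)) paste(ifelse(v, "true", "false"), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  writeLines(paste0(keys, " = ", vapply(config[keys], fmt, character(1))),
             path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*)$", ln,
                                perl = TRUE))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    vals <- strsplit(trimws(m[3]), ",")[[1]]
    v <- suppressWarnings(as.numeric(vals))
    if (!any(is.na(v))) out[[m[2]]] <- v
    else if (all(vals %in% c("true", "false"))) out[[m[2]]] <- vals == "true"
    else out[[m[2]]] <- vals
  }
  out
}

#' Hash of a run configuration
#'
#' MD5 over the canonical serialized form; used for output provenance.
#'
#' @param config named list
#' @return hex string
#' @export
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeRunConfig(config, tmp)
  unname(tools::md5sum(tmp))
}
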