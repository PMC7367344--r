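#' Write a trajectory (or single frame) as extended XYZ
#'
#' One block per frame: particle count, a comment line carrying the cubic
#' lattice, the per-column properties and the time stamp, then one row per
#' particle (species label, position, velocity, radius, mass).  Values are
#' written with full double precision so that reading the file back
#' reproduces the frames bit-exactly.
#'
#' @param x a `"gel_trajectory"` or `"particle_frame"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(x, path) {
  frames <- if (inherits(x, "gel_trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    n <- nrow(f$positions)
    lat <- sprintf("%.17g 0 0 0 %.17g 0 0 0 %.17g", f$box, f$box, f$box)
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:velo:R:3:radius:R:1:mass:R:1 Time=%.17g',
      lat, f$time), con)
    vel <- f$velocities
    if (is.null(vel) || !all(dim(vel) == c(n, 3)) || anyNA(vel))
      vel <- matrix(0, n, 3)
    sp <- ifelse(f$species == 0L, "a", "b")
    rows <- sprintf("%s %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                    sp, f$positions[, 1], f$positions[, 2], f$positions[, 3],
                    vel[, 1], vel[, 2], vel[, 3], f$radii, f$mass)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Counterpart of [write_extxyz()]; also accepts minimal XYZ files whose
#' comment line carries at least a `Lattice` entry.
#'
#' @param path file path.
#' @return A `"gel_trajectory"` (with `config = NULL`).
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed extended-XYZ: expected particle count at line ", i)
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    if (is.na(lat)) stop("extended-XYZ comment line lacks a Lattice entry")
    latv <- as.numeric(strsplit(trimws(lat), "\\s+")[[1]])
    box <- latv[1]
    tm <- regmatches(comment, regexec("Time=([0-9eE+.-]+)", comment))[[1]][2]
    tm <- if (is.na(tm)) 0 else as.numeric(tm)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    mat <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
    sp <- vapply(parts, `[`, character(1), 1L)
    frames[[length(frames) + 1L]] <- particle_frame(
      positions = mat[, 1:3, drop = FALSE],
      velocities = if (ncol(mat) >= 6) mat[, 4:6, drop = FALSE] else NULL,
      species = as.integer(sp != "a"),
      radii = if (ncol(mat) >= 7) mat[, 7] else NULL,
      mass = if (ncol(mat) >= 8) mat[, 8] else NULL,
      box = box, time = tm)
    i <- i + 2L + n
  }
  structure(list(frames = frames, config = NULL, log = NULL),
            class = "gel_trajectory")
}

#' Read a point cloud from CSV
#'
#' Plain coordinate tables (columns `x`, `y`, `z` and optionally `radius`),
#' the format produced by particle-tracking experiments.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `x`, `y`, `z` (and `radius` if present).
#' @export
read_point_cloud <- function(path) {
  df <- utils::read.csv(path)
  names(df) <- tolower(names(df))
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  df
}
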