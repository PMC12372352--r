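# Core data types and CSV plumbing for single-particle tracking tables.
#
# Canonical internal length unit is the micrometer; time is in seconds.
# Microrheology converts to SI internally (see rheology.R).

#' Boltzmann constant (J/K)
#' @keywords internal
.kB <- 1.380649e-23

#' Single-particle trajectory
#'
#' Constructs a planar trajectory: ordered positions of one particle sampled
#' at a fixed frame interval. Positions are in micrometers, `dt` in seconds.
#'
#' @param x,y Numeric vectors of positions (micrometers), equal length >= 2.
#' @param dt Frame interval in seconds (default 1, i.e. 1 Hz acquisition).
#' @param frames Integer frame indices, strictly increasing; defaults to
#'   `seq_along(x)`.
#' @param particle_id Identifier kept for provenance.
#' @return An object of class `sptraj`: a list with elements `particle_id`,
#'   `frames`, `x`, `y`, `dt`.
#' @export
trajectory <- function(x, y, dt = 1, frames = seq_along(x), particle_id = "p1") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("a trajectory needs at least 2 positions")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("positions must be finite")
  frames <- as.integer(frames)
  if (length(frames) != length(x)) stop("frames must match positions in length")
  if (any(diff(frames) <= 0L)) stop("frame indices must be strictly increasing")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be a positive scalar")
  structure(list(particle_id = particle_id, frames = frames, x = x, y = y, dt = dt),
            class = "sptraj")
}

#' @export
print.sptraj <- function(x, ...) {
  cat(sprintf("<sptraj> particle %s: %d positions, dt = %g s, extent %.3g um\n",
              as.character(x$particle_id), length(x$x), x$dt, .max_extent(x)))
  invisible(x)
}

#' @export
length.sptraj <- function(x) length(x$x)

#' @export
as.data.frame.sptraj <- function(x, ...) {
  data.frame(particle = x$particle_id, frame = x$frames, x = x$x, y = x$y)
}

# largest pairwise distance between positions (um)
.max_extent <- function(traj) {
  if (length(traj$x) > 1500L) {
    # chunk to bound memory on very long tracks
    return(sqrt(max(.max_sq_extent_chunked(traj$x, traj$y))))
  }
  max(stats::dist(cbind(traj$x, traj$y)))
}

.max_sq_extent_chunked <- function(x, y, chunk = 512L) {
  n <- length(x); best <- 0
  for (i in seq(1L, n, by = chunk)) {
    idx <- i:min(i + chunk - 1L, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    best <- max(best, max(d2))
  }
  best
}

# per-frame displacement vectors, an (N-1) x 2 matrix
.steps <- function(traj) cbind(diff(traj$x), diff(traj$y))

# per-frame step lengths (um)
.step_lengths <- function(traj) {
  s <- .steps(traj)
  sqrt(s[, 1]^2 + s[, 2]^2)
}

#' Particle and medium context
#'
#' Metadata needed to interpret a trajectory physically: tracer radius,
#' surface-charge label, nominal diameter, medium label, temperature and
#' dimensionality. The generalized Stokes-Einstein conversion uses
#' `radius_a` (meters), `temperature_T` (kelvin) and `dimensionality_d`.
#'
#' @param radius_a Particle radius in meters (> 0).
#' @param charge `"positive"` or `"negative"`.
#' @param nominal_diameter Nominal diameter in nanometers (100, 200 or 1000
#'   for the canonical study grid; other values allowed).
#' @param medium Medium label; canonical labels are `"PNCM"`, `"PACM-HEC"`,
#'   `"PACM-PAA"` (native porcine colonic mucus and the two artificial
#'   colonic mucus models).
#' @param temperature_T Absolute temperature in kelvin (default 310.15,
#'   i.e. 37 C).
#' @param dimensionality_d 2 for planar tracking (default) or 3.
#' @return An object of class `particle_context`.
#' @export
particle_context <- function(radius_a, charge = "negative",
                             nominal_diameter = radius_a * 2e9,
                             medium = "unknown",
                             temperature_T = 310.15, dimensionality_d = 2L) {
  if (!is.numeric(radius_a) || radius_a <= 0) stop("radius_a must be > 0 (meters)")
  if (!dimensionality_d %in% c(2L, 3L)) stop("dimensionality_d must be 2 or 3")
  if (temperature_T <= 0) stop("temperature_T must be > 0 (kelvin)")
  charge <- match.arg(charge, c("positive", "negative"))
  structure(list(radius_a = radius_a, charge = charge,
                 nominal_diameter = nominal_diameter, medium = medium,
                 temperature_T = temperature_T,
                 dimensionality_d = as.integer(dimensionality_d)),
            class = "particle_context")
}

#' @export
print.particle_context <- function(x, ...) {
  cat(sprintf("<particle_context> a = %.3g m (%g nm nominal, %s), medium %s, T = %g K, d = %d\n",
              x$radius_a, x$nominal_diameter, x$charge, x$medium,
              x$temperature_T, x$dimensionality_d))
  invisible(x)
}

#' Read trajectories from a tracking-table CSV
#'
#' Reads a tidy tracking table (one row per particle per frame) in the
#' dialect of common tracking software and returns one [trajectory()] per
#' particle. Positions are rescaled to micrometers via `length_unit`.
#'
#' @param path CSV file path.
#' @param dt Frame interval in seconds.
#' @param length_unit Micrometers per input length unit (e.g. `0.001` for
#'   positions recorded in nanometers, or the pixel size in um for pixel
#'   coordinates).
#' @param columns Named character vector mapping the required roles
#'   `particle`, `frame`, `x`, `y` to column names in the file.
#' @param frame_gaps `"reject"` (default) errors on non-contiguous frame
#'   numbering within a particle; `"contiguous"` keeps the rows and treats
#'   successive rows as `dt`-spaced.
#' @return A list of `sptraj` objects, named by particle id.
#' @export
read_trajectories <- function(path, dt = 1, length_unit = 1,
                              columns = c(particle = "particle", frame = "frame",
                                          x = "x", y = "y"),
                              frame_gaps = c("reject", "contiguous")) {
  frame_gaps <- match.arg(frame_gaps)
  need <- c("particle", "frame", "x", "y")
  if (!all(need %in% names(columns))) stop("columns must map particle, frame, x, y")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(columns[need]), names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(particle = tab[[columns[["particle"]]]],
                   frame = as.integer(tab[[columns[["frame"]]]]),
                   x = as.numeric(tab[[columns[["x"]]]]) * length_unit,
                   y = as.numeric(tab[[columns[["y"]]]]) * length_unit)
  dup <- duplicated(df[, c("particle", "frame")])
  if (any(dup)) {
    bad <- unique(paste0(df$particle[dup], "@", df$frame[dup]))
    stop("duplicate (particle, frame) rows: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  df <- df[order(df$particle, df$frame), ]
  out <- lapply(split(df, df$particle), function(d) {
    if (frame_gaps == "reject" && any(diff(d$frame) != 1L)) {
      stop("particle ", d$particle[1L], " has gaps in frame numbering; ",
           "use frame_gaps = \"contiguous\" to accept")
    }
    trajectory(d$x, d$y, dt = dt, frames = d$frame, particle_id = d$particle[1L])
  })
  out[order(names(out))]
}

#' Write trajectories to a tracking-table CSV
#'
#' Inverse of [read_trajectories()]: writes `particle,frame,x,y` rows in
#' micrometers.
#'
#' @param trajs List of `sptraj` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (length(trajs) == 0L) stop("refusing to write an empty trajectory set")
  df <- do.call(rbind, lapply(trajs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fingerprint table to CSV
#'
#' Floats are written at full double precision so a read-back reproduces the
#' table to better than 1e-9.
#'
#' @param table A `fingerprint_table` (or plain data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("refusing to write an empty fingerprint table")
  }
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE, scientific = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a fingerprint table written by [write_fingerprints()]
#'
#' @param path CSV path.
#' @return A `fingerprint_table` data frame.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if ("flagged" %in% names(df)) df$flagged <- as.logical(df$flagged)
  as_fingerprint_table(df)
}
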