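#' Single time sample of the flow solution
#'
#' Holds node positions, velocity and pressure at one instant. Positions equal
#' the mesh reference coordinates in rigid runs and the deformed coordinates
#' in moving-wall runs. All quantities are SI (m, m/s, Pa).
#'
#' @param mesh The [tcpcMesh()] the fields live on.
#' @param time Sample time in s.
#' @param velocity n x 3 matrix of nodal velocities (m/s).
#' @param pressure Length-n vector of nodal static pressure (Pa).
#' @param positions Optional n x 3 node positions (defaults to the mesh
#'   reference coordinates).
#' @return An object of class `field_frame`.
#' @export
fieldFrame <- function(mesh, time, velocity, pressure, positions = NULL) {
  stopifnot(inherits(mesh, "tcpc_mesh"))
  n <- nrow(mesh$nodes)
  if (is.null(positions)) positions <- mesh$nodes
  positions <- as.matrix(positions)
  velocity <- as.matrix(velocity)
  if (nrow(positions) != n || nrow(velocity) != n || length(pressure) != n) {
    stop(sprintf("field cardinality mismatch: mesh has %d nodes", n))
  }
  if (any(!is.finite(velocity)) || any(!is.finite(pressure)) ||
      any(!is.finite(positions))) {
    stop("non-finite field values")
  }
  structure(list(mesh = mesh, time = time, positions = positions,
                 velocity = velocity, pressure = as.numeric(pressure)),
            class = "field_frame")
}

#' @export
print.field_frame <- function(x, ...) {
  cat(sprintf("Field frame at t = %g s: |v| in [%.3g, %.3g] m/s, p in [%.3g, %.3g] Pa\n",
              x$time, min(sqrt(rowSums(x$velocity^2))),
              max(sqrt(rowSums(x$velocity^2))), min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' Ordered series of field frames over one or more cardiac cycles
#'
#' @param mesh Shared [tcpcMesh()] (connectivity identical for all frames).
#' @param frames List of [fieldFrame()]s with strictly increasing times.
#' @param period Cardiac cycle period in s.
#' @param periodic Declare the series periodic: the first and last frame
#'   fields must then agree within `periodic_tol` (relative).
#' @param periodic_tol Relative tolerance for the periodicity check.
#' @return An object of class `field_series`.
#' @export
fieldSeries <- function(mesh, frames, period, periodic = TRUE,
                        periodic_tol = 1e-8) {
  if (length(frames) == 0) stop("empty frame list")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0)) stop("non-monotone times")
  n <- nrow(mesh$nodes)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (nrow(f$positions) != n || nrow(f$velocity) != n ||
        length(f$pressure) != n) {
      stop(sprintf("frame %d has wrong node count", i))
    }
  }
  if (periodic && length(frames) > 1) {
    f1 <- frames[[1]]
    fN <- frames[[length(frames)]]
    sc <- max(abs(f1$velocity), 1e-12)
    sp <- max(abs(f1$pressure), 1e-12)
    if (max(abs(f1$velocity - fN$velocity)) > periodic_tol * sc ||
        max(abs(f1$pressure - fN$pressure)) > periodic_tol * sp) {
      stop("series declared periodic but first/last frames differ")
    }
  }
  n_cycles <- if (length(times) > 1) (max(times) - min(times)) / period else 0
  structure(list(mesh = mesh, frames = frames, times = times,
                 period = period, periodic = periodic,
                 n_cycles_stored = n_cycles),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("Field series: %d frames on [%g, %g] s (period %g s, %.2f cycles)\n",
              length(x$frames), min(x$times), max(x$times), x$period,
              x$n_cycles_stored))
  print(x$mesh)
  invisible(x)
}

#' Extract the frame at (or nearest to) a given time
#'
#' @param series A [fieldSeries()].
#' @param time Requested time in s.
#' @return The stored [fieldFrame()] whose time is closest to `time`.
#' @export
frameAt <- function(series, time) {
  series$frames[[which.min(abs(series$times - time))]]
}
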