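#' Scalar waveform
#'
#' A unit-tagged scalar time series (area, flow, volume, pressure, power).
#' Times must be strictly increasing and the same length as the values.
#'
#' @param times Sample times in s, strictly increasing.
#' @param values Scalar samples, same length as `times`.
#' @param unit Unit tag, e.g. `"cm^2"`, `"mL/s"`, `"mL"`, `"mmHg"`, `"mW"`.
#' @return An object of class `scalar_waveform` with fields `times`, `values`,
#'   `unit`.
#' @examples
#' w <- scalarWaveform(seq(0, 0.86, by = 0.01), sin(seq(0, 0.86, by = 0.01)), "mL/s")
#' waveformMean(w)
#' @export
scalarWaveform <- function(times, values, unit = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) == 0L) stop("waveform must have at least one sample")
  if (length(times) != length(values)) {
    stop("times and values must have the same length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("non-monotone times")
  }
  if (any(!is.finite(values)) || any(!is.finite(times))) {
    stop("waveform samples must be finite")
  }
  structure(list(times = times, values = values, unit = unit),
            class = "scalar_waveform")
}

#' @export
print.scalar_waveform <- function(x, ...) {
  cat(sprintf("Scalar waveform [%s]: %d samples on [%g, %g] s, range [%g, %g]\n",
              x$unit, length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Time average of a waveform by the trapezoidal rule
#'
#' @param w A [scalarWaveform()].
#' @return Trapezoid integral divided by the time span; for a single sample,
#'   the sample itself.
#' @export
waveformMean <- function(w) {
  stopifnot(inherits(w, "scalar_waveform"))
  if (length(w$times) == 1L) return(w$values)
  span <- w$times[length(w$times)] - w$times[1L]
  pracma::trapz(w$times, w$values) / span
}

#' Peak-to-peak range of a waveform
#'
#' @param w A [scalarWaveform()].
#' @return `max(values) - min(values)`.
#' @export
waveformRange <- function(w) {
  stopifnot(inherits(w, "scalar_waveform"))
  max(w$values) - min(w$values)
}

# restrict a waveform to times in [t0, t1] (inclusive)
waveformWindow <- function(w, t0, t1) {
  keep <- w$times >= t0 - 1e-12 & w$times <= t1 + 1e-12
  scalarWaveform(w$times[keep], w$values[keep], w$unit)
}
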