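# Energy metrics: pressure drop, control-volume power loss, cycle summaries
# and rigid-vs-compliant report differencing.

#' Pressure drop between two cap patches
#'
#' Area-averaged static pressure on `from_patch` minus area-averaged static
#' pressure on `to_patch`, in mmHg. (Clinically: Fontan pathway to left
#' pulmonary artery.)
#'
#' @param frame A [fieldFrame()].
#' @param from_patch,to_patch Cap patch labels.
#' @return Pressure drop in mmHg.
#' @export
pressureDrop <- function(frame, from_patch = "FP", to_patch = "LPA") {
  pf <- patchAverage(frame, from_patch, frame$pressure)$average
  pt <- patchAverage(frame, to_patch, frame$pressure)$average
  mmHgFromPa(pf - pt)
}

#' Instantaneous control-volume power loss
#'
#' Net rate of mechanical energy (static pressure plus kinetic) flowing into
#' the connection through its cap patches:
#' \deqn{PL = -\sum_{caps} \int (p + \tfrac12 \rho |v|^2)\, (v \cdot \hat n_{out})\, dA}
#' Positive when energy is dissipated inside; instantaneous values may be
#' negative under pulsatile flow. Facet integrals use the edge-midpoint rule
#' (exact for quadratics).
#'
#' @param frame A [fieldFrame()].
#' @param constants [physicalConstants()] (density enters the kinetic term).
#' @return Power loss in mW.
#' @export
powerLoss <- function(frame, constants = physicalConstants()) {
  mesh <- frame$mesh
  rho <- constants$density
  total <- 0
  for (patch in capNames(mesh)) {
    idx <- patchFacets(mesh, patch)
    f <- mesh$facets[idx, , drop = FALSE]
    p1 <- frame$positions[f[, 1], , drop = FALSE]
    e1 <- frame$positions[f[, 2], , drop = FALSE] - p1
    e2 <- frame$positions[f[, 3], , drop = FALSE] - p1
    av <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
    area <- sqrt(rowSums(av^2))
    nhat <- av / area
    # nodal energy flux density evaluated at the three edge midpoints
    vals <- lapply(1:3, function(k) {
      i <- f[, k]
      j <- f[, k %% 3 + 1]
      vm <- (frame$velocity[i, , drop = FALSE] +
               frame$velocity[j, , drop = FALSE]) / 2
      pm <- (frame$pressure[i] + frame$pressure[j]) / 2
      (pm + 0.5 * rho * rowSums(vm^2)) * rowSums(vm * nhat)
    })
    total <- total + sum(area / 3 * (vals[[1]] + vals[[2]] + vals[[3]]))
  }
  mWFromW(-total)
}

#' Waveforms of pressure drop and power loss over a series
#'
#' @param series A [fieldSeries()].
#' @param from_patch,to_patch Patches for the pressure drop.
#' @param constants [physicalConstants()].
#' @return `pressureDropWaveform`: [scalarWaveform()] in mmHg;
#'   `powerLossWaveform`: [scalarWaveform()] in mW.
#' @export
pressureDropWaveform <- function(series, from_patch = "FP", to_patch = "LPA") {
  scalarWaveform(series$times,
                 vapply(series$frames, pressureDrop, numeric(1),
                        from_patch = from_patch, to_patch = to_patch),
                 "mmHg")
}

#' @rdname pressureDropWaveform
#' @export
powerLossWaveform <- function(series, constants = physicalConstants()) {
  scalarWaveform(series$times,
                 vapply(series$frames, powerLoss, numeric(1),
                        constants = constants),
                 "mW")
}

# min/max/average stats of a waveform over its last whole cycle
.cycleStats <- function(w, period) {
  t_end <- max(w$times)
  span <- t_end - min(w$times)
  if (span < period * (1 - 1e-9)) {
    stop("waveform covers less than one full cycle")
  }
  ww <- waveformWindow(w, t_end - period, t_end)
  c(min = min(ww$values), max = max(ww$values), average = waveformMean(ww))
}

#' Hemodynamic cycle report
#'
#' Minimum, maximum and trapezoid time-average of the pressure-drop and
#' power-loss waveforms over the last stored full cycle, or a report built
#' directly from given statistics.
#'
#' @param pressure_drop Either a [scalarWaveform()] (mmHg) or a named vector
#'   `c(min=, max=, average=)`.
#' @param power_loss Either a [scalarWaveform()] (mW) or a named stats vector.
#' @param period Cycle period in s (required when waveforms are given).
#' @param label Report label, e.g. `"rigid"` or `"compliant"`.
#' @return Object of class `hemo_report` with `pressure_drop` and
#'   `power_loss` stats (each `min`, `max`, `average`, `range`) and `label`.
#' @export
hemoReport <- function(pressure_drop, power_loss, period = NULL,
                       label = "unlabeled") {
  asStats <- function(x, what) {
    if (inherits(x, "scalar_waveform")) {
      if (is.null(period)) stop("period required to summarize waveforms")
      s <- .cycleStats(x, period)
    } else {
      s <- x[c("min", "max", "average")]
    }
    slack <- 1e-9 * max(abs(s), 1e-12)
    if (!(s["min"] <= s["average"] + slack && s["average"] <= s["max"] + slack)) {
      stop(sprintf("inconsistent %s stats: need min <= average <= max", what))
    }
    s["average"] <- min(max(s["average"], s["min"]), s["max"])
    c(s, range = unname(s["max"] - s["min"]))
  }
  structure(
    list(pressure_drop = asStats(pressure_drop, "pressure drop"),
         power_loss = asStats(power_loss, "power loss"),
         label = label),
    class = "hemo_report"
  )
}

#' Summarize a series into a hemodynamic report
#'
#' Convenience wrapper: computes pressure-drop and power-loss waveforms and
#' their last-cycle statistics.
#'
#' @param series A [fieldSeries()].
#' @param label Report label.
#' @param from_patch,to_patch Pressure-drop patches.
#' @param constants [physicalConstants()].
#' @return A [hemoReport()], with the waveforms attached as `waveforms`.
#' @export
summarizeHemodynamics <- function(series, label = "unlabeled",
                                  from_patch = "FP", to_patch = "LPA",
                                  constants = physicalConstants()) {
  pd <- pressureDropWaveform(series, from_patch, to_patch)
  pl <- powerLossWaveform(series, constants)
  rep <- hemoReport(pd, pl, period = series$period, label = label)
  rep$waveforms <- list(pressure_drop = pd, power_loss = pl)
  rep
}

#' @export
print.hemo_report <- function(x, ...) {
  cat(sprintf("Hemodynamic report (%s):\n", x$label))
  cat(sprintf("  pressure drop [mmHg]: min %.2f  max %.2f  average %.2f\n",
              x$pressure_drop["min"], x$pressure_drop["max"],
              x$pressure_drop["average"]))
  cat(sprintf("  power loss    [mW]:   min %.2f  max %.2f  average %.2f\n",
              x$power_loss["min"], x$power_loss["max"],
              x$power_loss["average"]))
  invisible(x)
}

#' Difference table between two hemodynamic reports
#'
#' Absolute differences of the time-averages and the fluctuation ranges
#' (max minus min) of each metric, for rigid-versus-compliant comparisons.
#'
#' @param a,b [hemoReport()]s with the same metric set.
#' @return Data frame with one row per metric: the two averages, the absolute
#'   average difference, the two fluctuation ranges, and their difference.
#' @examples
#' ra <- hemoReport(c(min = -0.60, max = 2.35, average = 0.60),
#'                  c(min = -4.46, max = 17.33, average = 2.89), label = "rigid")
#' rb <- hemoReport(c(min = -0.07, max = 1.13, average = 0.61),
#'                  c(min = -0.82, max = 9.34, average = 2.99), label = "compliant")
#' compareReports(ra, rb)
#' @export
compareReports <- function(a, b) {
  stopifnot(inherits(a, "hemo_report"), inherits(b, "hemo_report"))
  metrics <- c("pressure_drop", "power_loss")
  units <- c(pressure_drop = "mmHg", power_loss = "mW")
  rows <- lapply(metrics, function(m) {
    sa <- a[[m]]
    sb <- b[[m]]
    data.frame(metric = m, unit = units[[m]],
               average_a = unname(sa["average"]),
               average_b = unname(sb["average"]),
               diff_average = abs(unname(sa["average"] - sb["average"])),
               range_a = unname(sa["range"]), range_b = unname(sb["range"]),
               diff_range = unname(sb["range"] - sa["range"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- c(a = a$label, b = b$label)
  out
}
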