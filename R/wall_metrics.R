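# Wall-deformation metrics: area waveforms, deformation index, net-flow
# volume integration, compliance estimation.

#' Cross-sectional area waveform of a branch
#'
#' Cuts every frame of a series with the same plane and collects the areas,
#' tracking wall motion through the frame node positions.
#'
#' @param series A [fieldSeries()].
#' @param plane `list(point, normal)` in m (see [crossSection()]).
#' @param branch Branch label for cut validation.
#' @return A [scalarWaveform()] in cm^2.
#' @export
areaWaveform <- function(series, plane, branch = NULL) {
  areas <- vapply(series$frames, function(f) {
    crossSection(f, plane, branch)$area_cm2
  }, numeric(1))
  scalarWaveform(series$times, areas, "cm^2")
}

#' Deformation index of an area waveform
#'
#' Quantifies the relative amplitude of cross-sectional area change over the
#' cycle:
#' \deqn{DI = \frac{A_{max} - A_{min}}{A_{mean}} \times 100\%}
#' where \eqn{A_{mean}} is the arithmetic mean of the sampled areas.
#'
#' @param areas A [scalarWaveform()] of positive areas (cm^2).
#' @return An object of class `deformation_index` with fields `A_max`,
#'   `A_min`, `A_mean` (cm^2) and `DI` (percent).
#' @examples
#' a <- scalarWaveform(0:10, 3.74 + 0.10 * rep(c(-1, 1), length.out = 11), "cm^2")
#' deformationIndex(a)  # DI close to 5.3 percent
#' @export
deformationIndex <- function(areas) {
  stopifnot(inherits(areas, "scalar_waveform"))
  if (length(areas$values) == 0) stop("empty area waveform")
  if (any(areas$values <= 0)) stop("areas must be positive")
  a_mean <- mean(areas$values)
  if (a_mean <= 0) stop("non-positive mean area")
  a_max <- max(areas$values)
  a_min <- min(areas$values)
  structure(
    list(A_max = a_max, A_min = a_min, A_mean = a_mean,
         DI = (a_max - a_min) / a_mean * 100),
    class = "deformation_index"
  )
}

#' @export
print.deformation_index <- function(x, ...) {
  cat(sprintf("Deformation index: %.1f%%  (A_mean %.2f cm^2, range %.2f cm^2)\n",
              x$DI, x$A_mean, x$A_max - x$A_min))
  invisible(x)
}

#' Net flow through the connection
#'
#' Per-frame total inflow minus total outflow, computed from the boundary
#' fluxes at the registered cap patches. Vanishes on rigid series (mass
#' closure) and equals the cavity volume rate dV/dt on moving-wall series.
#'
#' @param series A [fieldSeries()].
#' @return A [scalarWaveform()] in mL/s.
#' @export
netFlowWaveform <- function(series) {
  patches <- series$mesh$patches
  inlets <- patches$name[patches$type == "inlet"]
  outlets <- patches$name[patches$type == "outlet"]
  if (length(inlets) == 0 || length(outlets) == 0) {
    stop("series mesh must register inlet and outlet patches")
  }
  net <- vapply(series$frames, function(f) {
    qin <- sum(vapply(inlets, function(p) boundaryFlux(f, p), numeric(1)))
    qout <- sum(vapply(outlets, function(p) boundaryFlux(f, p), numeric(1)))
    qin - qout
  }, numeric(1))
  scalarWaveform(series$times, net, "mL/s")
}

#' Volume waveform by trapezoidal integration of the net flow
#'
#' @param net_flow A [scalarWaveform()] in mL/s.
#' @param V0 Initial volume in mL.
#' @return A [scalarWaveform()] in mL with `V(t0) = V0`.
#' @export
volumeWaveform <- function(net_flow, V0) {
  stopifnot(inherits(net_flow, "scalar_waveform"))
  v <- V0 + as.vector(pracma::cumtrapz(net_flow$times, net_flow$values))
  scalarWaveform(net_flow$times, v, "mL")
}

#' Volume-averaged pressure waveform
#'
#' Cell-volume-weighted average of the nodal pressure over the whole
#' connection, per frame, reported in mmHg.
#'
#' @param series A [fieldSeries()].
#' @return A [scalarWaveform()] in mmHg.
#' @export
volumeAveragedPressure <- function(series) {
  mesh <- series$mesh
  p <- vapply(series$frames, function(f) {
    vol <- tetVolumes(mesh$tets, f$positions)
    pc <- (f$pressure[mesh$tets[, 1]] + f$pressure[mesh$tets[, 2]] +
             f$pressure[mesh$tets[, 3]] + f$pressure[mesh$tets[, 4]]) / 4
    sum(vol * pc) / sum(vol)
  }, numeric(1))
  scalarWaveform(series$times, mmHgFromPa(p), "mmHg")
}

#' Estimate connection compliance from volume and pressure waveforms
#'
#' Divides the maximum cyclic volume change by the maximum change of the
#' volume-averaged pressure: \eqn{C = \Delta V_{max} / \Delta P_{max}}.
#'
#' @param volume [scalarWaveform()] in mL.
#' @param pressure [scalarWaveform()] of volume-averaged pressure in mmHg.
#' @return Object of class `compliance_estimate` with `dV_max` (mL),
#'   `dP_max` (mmHg) and `C` (mL/mmHg).
#' @examples
#' v <- scalarWaveform(c(0, 0.4, 0.86), c(62.49, 64.46, 62.49), "mL")
#' p <- scalarWaveform(c(0, 0.4, 0.86), c(0.07, 0.87, 0.07), "mmHg")
#' estimateCompliance(v, p)  # 1.97 / 0.8 = 2.46 mL/mmHg
#' @export
estimateCompliance <- function(volume, pressure) {
  stopifnot(inherits(volume, "scalar_waveform"),
            inherits(pressure, "scalar_waveform"))
  dV <- waveformRange(volume)
  dP <- waveformRange(pressure)
  C <- if (dV == 0) 0 else {
    if (dP <= 0) stop("zero pressure range: compliance undefined")
    dV / dP
  }
  structure(list(dV_max = dV, dP_max = dP, C = C),
            class = "compliance_estimate")
}

#' @export
print.compliance_estimate <- function(x, ...) {
  cat(sprintf("Compliance estimate: %.2f mL/mmHg (dV %.2f mL / dP %.2f mmHg)\n",
              x$C, x$dV_max, x$dP_max))
  invisible(x)
}
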