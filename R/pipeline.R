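# Orchestration: rigid-versus-compliant comparison workflow and the
# mesh-refinement study harness.

#' Rigid-versus-compliant comparison workflow
#'
#' Runs the full hemodynamic comparison between a rigid and a compliant
#' (moving-wall) field series sharing the same patch labels and period:
#' energy reports ([summarizeHemodynamics()]), particle transport
#' ([seedParticles()], [advectParticles()], [residenceStats()], [hfd()]),
#' and the report difference table ([compareReports()]). Optionally writes
#' a JSON/CSV bundle.
#'
#' @param rigid A [fieldSeries()] (or a manifest path) for the rigid run.
#' @param compliant A [fieldSeries()] (or a manifest path) for the
#'   compliant run.
#' @param protocol A [seedingProtocol()]; the default is a desk-scale
#'   preset (reduced seed count) covering one seeding cycle plus the
#'   configured horizon.
#' @param substep RK4 substep in s for the advection.
#' @param constants [physicalConstants()].
#' @param out_dir Optional output directory for `comparison.json` and
#'   `comparison.csv`.
#' @return Object of class `tcpc_comparison`: per-condition reports,
#'   washout and HFD results, the difference table, and provenance
#'   (package version, seeds, problem sizes).
#' @export
runComparison <- function(rigid, compliant, protocol = NULL, substep = NULL,
                          constants = physicalConstants(), out_dir = NULL) {
  load <- function(x, what) {
    if (inherits(x, "field_series")) return(x)
    if (is.character(x)) return(readFieldSeries(x))
    stop("missing or invalid ", what, " series")
  }
  rigid <- load(rigid, "rigid")
  compliant <- load(compliant, "compliant")
  if (!setequal(capNames(rigid$mesh), capNames(compliant$mesh))) {
    stop("mismatched patch labels between the two series")
  }
  if (abs(rigid$period - compliant$period) > 1e-12) {
    stop("mismatched periods between the two series")
  }
  if (is.null(protocol)) {
    protocol <- seedingProtocol(interval = rigid$period / 20,
                                duration = rigid$period,
                                seeds_per_event = 10, horizon_cycles = 5)
  }
  one <- function(series, label) {
    rep <- summarizeHemodynamics(series, label = label, constants = constants)
    ens <- advectParticles(seedParticles(series, protocol), series,
                           substep = substep)
    list(report = rep,
         washout = suppressWarnings(residenceStats(ens)),
         hfd = hfd(ens),
         ensemble = ens)
  }
  rr <- one(rigid, "rigid")
  cc <- one(compliant, "compliant")
  diff_table <- compareReports(rr$report, cc$report)
  washout_order <- if (!is.na(rr$washout$W95) && !is.na(cc$washout$W95)) {
    cc$washout$W95 <= rr$washout$W95
  } else NA
  out <- structure(
    list(rigid = rr, compliant = cc, differences = diff_table,
         compliant_washout_not_slower = washout_order,
         provenance = list(
           package_version = as.character(utils::packageVersion("tcpcflow")),
           protocol = unclass(protocol),
           n_particles = nrow(rr$ensemble$particles),
           n_frames = length(rigid$frames),
           n_cells = nrow(rigid$mesh$tets))),
    class = "tcpc_comparison"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(comparisonAsList(out),
                         file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(diff_table, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  out
}

# serializable summary of a comparison
comparisonAsList <- function(x) {
  side <- function(s) {
    list(pressure_drop = as.list(s$report$pressure_drop),
         power_loss = as.list(s$report$power_loss),
         W95 = s$washout$W95, W95_cycles = s$washout$W95_cycles,
         exited_fraction = unname(s$washout$counts["exited"] /
                                    s$washout$counts["seeded"]),
         hfd_lpa = s$hfd$hfd_lpa)
  }
  list(rigid = side(x$rigid), compliant = side(x$compliant),
       differences = x$differences,
       compliant_washout_not_slower = x$compliant_washout_not_slower,
       provenance = x$provenance)
}

#' @export
print.tcpc_comparison <- function(x, ...) {
  cat("Rigid vs compliant comparison\n")
  print(x$rigid$report)
  print(x$compliant$report)
  cat(sprintf("  |d average pressure drop| = %.3g mmHg; |d average power loss| = %.3g mW\n",
              x$differences$diff_average[1], x$differences$diff_average[2]))
  cat(sprintf("  W95: rigid %.3g s, compliant %.3g s; HFD(LPA): rigid %.1f%%, compliant %.1f%%\n",
              x$rigid$washout$W95, x$compliant$washout$W95,
              x$rigid$hfd$hfd_lpa, x$compliant$hfd$hfd_lpa))
  invisible(x)
}

#' Mesh-refinement study on the Poiseuille fixture
#'
#' Builds the steady pipe fixture at a sequence of mesh edge lengths and
#' tabulates pressure drop, power loss and inlet cap area per resolution,
#' their percent errors against the analytic closed forms, and pairwise
#' percent differences between successive resolutions.
#'
#' @param edge_lengths_mm Decreasing (coarse to fine) edge lengths in mm;
#'   at least two.
#' @param radius_cm,length_cm,flow_ml_s Pipe fixture parameters.
#' @param constants [physicalConstants()].
#' @return Object of class `refinement_study` with the per-resolution table
#'   and the pairwise difference table.
#' @export
refinementStudy <- function(edge_lengths_mm, radius_cm = 0.5, length_cm = 5,
                            flow_ml_s = 10, constants = physicalConstants()) {
  if (length(edge_lengths_mm) < 2) stop("need >=2 edge lengths")
  rows <- lapply(edge_lengths_mm, function(e) {
    fx <- poiseuilleFixture(radius_cm, length_cm, flow_ml_s, constants, e)
    fr <- fx$frames[[1]]
    pd <- pressureDrop(fr, "FP", "LPA")
    pl <- powerLoss(fr, constants)
    area <- crossSection(fr, list(point = c(0, 0, 0.5 * fx$mesh$pipe$length),
                                  normal = c(0, 0, 1)))$area_cm2
    data.frame(edge_mm = e,
               n_cells = nrow(fx$mesh$tets),
               pressure_drop_mmHg = pd,
               power_loss_mW = pl,
               area_cm2 = area)
  })
  tab <- do.call(rbind, rows)
  pd_exact <- mmHgFromPa(8 * constants$dynamic_viscosity * (length_cm / 100) *
                           (flow_ml_s * 1e-6) / (pi * (radius_cm / 100)^4))
  pl_exact <- mWFromW(paFromMmHg(pd_exact) * flow_ml_s * 1e-6)
  area_exact <- pi * radius_cm^2
  tab$pct_err_pressure_drop <- 100 * abs(tab$pressure_drop_mmHg - pd_exact) / pd_exact
  tab$pct_err_power_loss <- 100 * abs(tab$power_loss_mW - pl_exact) / pl_exact
  tab$pct_err_area <- 100 * abs(tab$area_cm2 - area_exact) / area_exact
  nr <- nrow(tab)
  pair <- data.frame(
    coarse_mm = tab$edge_mm[-nr], fine_mm = tab$edge_mm[-1],
    pct_diff_power_loss = 100 * abs(tab$power_loss_mW[-nr] - tab$power_loss_mW[-1]) /
      abs(tab$power_loss_mW[-1]),
    diff_pressure_drop_mmHg = abs(tab$pressure_drop_mmHg[-nr] -
                                    tab$pressure_drop_mmHg[-1])
  )
  structure(list(table = tab, pairwise = pair,
                 exact = c(pressure_drop_mmHg = pd_exact,
                           power_loss_mW = pl_exact, area_cm2 = area_exact)),
            class = "refinement_study")
}

#' @export
print.refinement_study <- function(x, ...) {
  cat("Mesh refinement study (Poiseuille fixture)\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("pairwise differences:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
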