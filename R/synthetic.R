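#' Configuration for the synthetic TCPC generator
#'
#' Defines the idealized four-branch junction geometry, the pulsatile inflow
#' waveforms, the outlet flow split, and the prescribed wall motion used to
#' emulate a compliant (FSI-like) solution. Geometric inputs are in clinical
#' units (cm, mm); everything is converted to SI internally.
#'
#' The inflow of each inlet is a Fourier series
#' \deqn{Q(t) = \bar Q \,[1 + \sum_k a_k \cos(k \omega t + \phi_k)]}
#' with \eqn{\omega = 2\pi/T}. The default means (FP 30 mL/s, SVC 20 mL/s)
#' give a resting total venous return of 3 L/min with the usual caval split;
#' the default harmonic content is mild, keeping the inflow strictly positive
#' as observed in resting Fontan phase-contrast data.
#'
#' In `moving` mode the wall of the Fontan-pathway arm is displaced radially
#' by \eqn{\epsilon \sin(2\pi t/T)\,\phi(s)} where \eqn{\phi} is a smooth
#' axial window vanishing outside `wall_window` (caps therefore stay fixed),
#' so cross-sectional area and cavity volume change in closed form (see
#' [movingVolumeChange()]). The default amplitude 0.013 reproduces a
#' deformation index of about 5 percent, the scale seen in compliant Fontan
#' pathways.
#'
#' @param radii Named vector, branch radii in cm (`FP`, `SVC`, `LPA`, `RPA`).
#' @param lengths Named vector, branch lengths in cm.
#' @param junction_offset Lateral caval offset in cm (shears the FP arm).
#' @param edge_length Target mesh edge length in mm.
#' @param cycle_period Cardiac cycle in s.
#' @param time_step Integrator substep in s (particle advection default).
#' @param frame_interval Stored-frame spacing in s.
#' @param inflow List with `FP` and `SVC` entries, each
#'   `list(mean = <mL/s>, harmonics = cbind(amp, phase))` (relative amplitude,
#'   phase in rad).
#' @param lpa_fraction Fraction of total outflow leaving via the LPA.
#' @param wall_amplitude Radial wall-motion amplitude (dimensionless).
#' @param wall_window Axial window of wall motion as fractions of the FP arm
#'   length; must lie inside the circular part of the arm.
#' @param wall_slip Near-wall slip fraction of the velocity profile. Passive
#'   tracers in a strictly no-slip kinematic field advect arbitrarily slowly
#'   near the wall (and freeze entirely in boundary cells whose nodes are all
#'   on the wall), so the generator uses the regularized profile
#'   \eqn{u \propto 1 - (1 - slip)\,\rho^2}, normalized to carry the branch
#'   flow exactly. Set to 0 for strict no-slip.
#' @param seed Random seed (seed-point jitter in particle seeding).
#' @return An object of class `synthetic_config`.
#' @export
syntheticConfig <- function(radii = c(FP = 1.09, SVC = 0.80, LPA = 0.60, RPA = 0.60),
                            lengths = c(FP = 3.0, SVC = 2.5, LPA = 2.5, RPA = 2.5),
                            junction_offset = 0,
                            edge_length = 2,
                            cycle_period = 0.86,
                            time_step = 5e-4,
                            frame_interval = cycle_period / 24,
                            inflow = list(
                              FP = list(mean = 30,
                                        harmonics = cbind(amp = c(0.35, 0.12),
                                                          phase = c(0, 0.6))),
                              SVC = list(mean = 20,
                                         harmonics = cbind(amp = c(0.30, 0.10),
                                                           phase = c(0, 1.0)))
                            ),
                            lpa_fraction = 0.5,
                            wall_amplitude = 0.013,
                            wall_window = c(0.45, 0.85),
                            wall_slip = 0.05,
                            seed = 1L) {
  branch_names <- c("FP", "SVC", "LPA", "RPA")
  stopifnot(all(branch_names %in% names(radii)),
            all(branch_names %in% names(lengths)),
            all(radii > 0), all(lengths > 0),
            cycle_period > 0, edge_length > 0, time_step > 0,
            frame_interval >= time_step,
            lpa_fraction >= 0, lpa_fraction <= 1,
            wall_amplitude >= 0, wall_amplitude <= 0.3,
            wall_slip >= 0, wall_slip < 1,
            junction_offset >= 0)
  transition_fraction <- 0.35
  if (wall_amplitude > 0 &&
      (wall_window[1] < transition_fraction + 0.05 || wall_window[2] > 0.95 ||
       wall_window[1] >= wall_window[2])) {
    stop("wall_window must lie within the circular part of the FP arm, ",
         "strictly inside (", transition_fraction + 0.05, ", 0.95)")
  }
  structure(
    list(
      radii = radii[branch_names], lengths = lengths[branch_names],
      radii_m = radii[branch_names] / 100,
      lengths_m = lengths[branch_names] / 100,
      junction_offset = junction_offset,
      junction_offset_m = junction_offset / 100,
      junction_half_width_m = 0.9 * max(radii) / 100,
      edge_length = edge_length, edge_length_m = edge_length / 1000,
      cycle_period = cycle_period, time_step = time_step,
      frame_interval = frame_interval,
      inflow = inflow, lpa_fraction = lpa_fraction,
      wall_amplitude = wall_amplitude, wall_window = wall_window,
      wall_slip = wall_slip,
      transition_fraction = transition_fraction,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic TCPC configuration\n")
  cat(sprintf("  radii (cm):  FP %.2f  SVC %.2f  LPA %.2f  RPA %.2f\n",
              x$radii["FP"], x$radii["SVC"], x$radii["LPA"], x$radii["RPA"]))
  cat(sprintf("  period %g s, edge %g mm, LPA fraction %.2f, wall amplitude %.3f\n",
              x$cycle_period, x$edge_length, x$lpa_fraction, x$wall_amplitude))
  invisible(x)
}

# inflow rate function for one inlet, in m^3/s
.inflowFun <- function(config, branch) {
  spec <- config$inflow[[branch]]
  omega <- 2 * pi / config$cycle_period
  mean_si <- spec$mean * 1e-6
  h <- spec$harmonics
  function(t) {
    q <- rep(1, length(t))
    if (!is.null(h) && nrow(h) > 0) {
      for (k in seq_len(nrow(h))) {
        q <- q + unname(h[k, "amp"]) * cos(k * omega * t + unname(h[k, "phase"]))
      }
    }
    mean_si * q
  }
}

#' Pulsatile inflow waveforms for the two inlets
#'
#' Evaluates the configured Fourier-series inflows at the stored-frame times
#' (or at supplied times) over one cycle.
#'
#' @param config A [syntheticConfig()].
#' @param times Optional times in s; defaults to one cycle at the configured
#'   frame interval.
#' @return List with `FP` and `SVC` [scalarWaveform()]s in mL/s.
#' @examples
#' wf <- makeInflowWaveforms(syntheticConfig())
#' waveformMean(wf$FP)  # configured mean, 30 mL/s
#' @export
makeInflowWaveforms <- function(config, times = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(times)) {
    nf <- max(2L, round(config$cycle_period / config$frame_interval))
    times <- seq(0, config$cycle_period, length.out = nf + 1)
  }
  lapply(list(FP = "FP", SVC = "SVC"), function(b) {
    scalarWaveform(times, .inflowFun(config, b)(times) * 1e6, "mL/s")
  })
}

# regularized Poiseuille profile factor: disc-mean 1, slip*u_scale at the wall
.profileFactor <- function(rho2, slip) {
  beta <- 1 - slip
  (1 - beta * rho2) / (1 - beta / 2)
}

# axial wall-motion window on the FP arm: phi(s) = sin^2 over [s0, s1], else 0
.wallWindowFun <- function(config) {
  L <- config$lengths_m[["FP"]]
  s0 <- config$wall_window[1] * L
  s1 <- config$wall_window[2] * L
  function(s) {
    phi <- numeric(length(s))
    inside <- s > s0 & s < s1
    phi[inside] <- sin(pi * (s[inside] - s0) / (s1 - s0))^2
    phi
  }
}

#' Closed-form cavity volume change of the prescribed wall motion
#'
#' The moving-wall series scales FP cross-sections by
#' \eqn{1 + \epsilon q(t) \phi(s)} with \eqn{q = \sin(2\pi t/T)} and the
#' sine-squared axial window \eqn{\phi}. Because the window lies in the
#' circular part of the arm (area \eqn{\pi R^2}), the volume change is
#' \deqn{\Delta V(t) = \pi R^2 L_w\, \epsilon q \left(1 + \tfrac38 \epsilon q\right)}
#' with \eqn{L_w} the window length, and its exact time derivative is
#' returned by `movingVolumeRate()`.
#'
#' @param config A [syntheticConfig()].
#' @param t Times in s.
#' @return `movingVolumeChange`: volume change vs. the rigid geometry, mL.
#' @export
movingVolumeChange <- function(config, t) {
  eps <- config$wall_amplitude
  R <- config$radii_m[["FP"]]
  L <- config$lengths_m[["FP"]]
  Lw <- diff(config$wall_window) * L
  q <- sin(2 * pi * t / config$cycle_period)
  (pi * R^2 * Lw * (eps * q + 3 / 8 * eps^2 * q^2)) * 1e6
}

#' @rdname movingVolumeChange
#' @return `movingVolumeRate`: rate of cavity volume change dV/dt, mL/s.
#' @export
movingVolumeRate <- function(config, t) {
  eps <- config$wall_amplitude
  R <- config$radii_m[["FP"]]
  L <- config$lengths_m[["FP"]]
  Lw <- diff(config$wall_window) * L
  omega <- 2 * pi / config$cycle_period
  q <- sin(omega * t)
  qd <- omega * cos(omega * t)
  (pi * R^2 * Lw * eps * qd * (1 + 3 / 4 * eps * q)) * 1e6
}

# instantaneous branch flows in m^3/s (outlets reduced by dV/dt in moving mode)
.branchFlows <- function(config, t, mode) {
  qfp <- .inflowFun(config, "FP")(t)
  qsvc <- .inflowFun(config, "SVC")(t)
  dv <- if (mode == "moving") movingVolumeRate(config, t) * 1e-6 else 0
  qout <- qfp + qsvc - dv
  lam <- config$lpa_fraction
  c(FP = qfp, SVC = qsvc, LPA = lam * qout, RPA = (1 - lam) * qout)
}

# Evaluate the synthetic velocity/pressure/positions at time t on the mesh
# built by buildIdealizedTcpc.
.synthFrame <- function(mesh, config, t, mode, constants = physicalConstants(
                          cycle_period = config$cycle_period)) {
  meta <- mesh$node_meta
  info <- mesh$branch_info
  a <- mesh$junction_half_width
  mu <- constants$dynamic_viscosity
  omega <- 2 * pi / config$cycle_period
  eps <- config$wall_amplitude
  q <- sin(omega * t)
  qd <- omega * cos(omega * t)
  phiFun <- .wallWindowFun(config)

  Qb <- .branchFlows(config, t, mode)
  n <- nrow(mesh$nodes)
  vel <- matrix(0, n, 3)
  prs <- numeric(n)
  pos <- mesh$nodes

  flow_sign <- c(FP = -1, SVC = -1, LPA = 1, RPA = 1)  # flow dir = sign * axis
  p_sign <- c(FP = 1, SVC = 1, LPA = -1, RPA = -1)     # inlets above junction p
  Kb <- vapply(names(info), function(b) 8 * mu / (pi * info[[b]]$radius^4),
               numeric(1))

  for (b in names(info)) {
    idx <- which(meta$region == b)
    if (length(idx) == 0) next
    bi <- info[[b]]
    st <- meta$station[idx]
    s <- meta$s[idx]
    area <- bi$area[st]
    if (mode == "moving" && b == "FP" && eps > 0) {
      phi <- phiFun(s)
      area <- area * (1 + eps * q * phi)^2
    }
    rho2 <- .rhoSq(meta$u[idx], meta$v[idx])
    vmag <- Qb[[b]] / area * .profileFactor(rho2, config$wall_slip)
    dir <- flow_sign[[b]] * .branchFrames[[b]]$axis
    vel[idx, ] <- outer(vmag, dir)
    prs[idx] <- p_sign[[b]] * Kb[[b]] * Qb[[b]] * (a + s)
  }

  # junction: partition-of-unity blend of the four branch fields extended
  # through the box
  jidx <- which(meta$region == "JUNCTION")
  if (length(jidx) > 0) {
    xj <- mesh$nodes[jidx, , drop = FALSE]
    delta <- 1e-9 * a
    wsum <- numeric(length(jidx))
    vacc <- matrix(0, length(jidx), 3)
    pacc <- numeric(length(jidx))
    for (b in names(info)) {
      fr <- .branchFrames[[b]]
      ca <- as.vector(xj %*% fr$axis)
      d <- pmax(a - ca, 0)
      wgt <- 1 / (d + delta)^2
      l1 <- as.vector(xj %*% fr$e1) / a
      l2 <- as.vector(xj %*% fr$e2) / a
      rho2 <- .rhoSq(l1, l2)
      vmag <- Qb[[b]] / (4 * a^2) * .profileFactor(rho2, config$wall_slip)
      dir <- flow_sign[[b]] * fr$axis
      vacc <- vacc + wgt * outer(vmag, dir)
      pacc <- pacc + wgt * (p_sign[[b]] * Kb[[b]] * Qb[[b]] * ca)
      wsum <- wsum + wgt
    }
    vel[jidx, ] <- vacc / wsum
    prs[jidx] <- pacc / wsum
  }

  # prescribed wall motion on the FP arm: radial scaling about the arm center
  # line, plus the corresponding mesh-motion velocity
  if (mode == "moving" && eps > 0) {
    idx <- which(meta$region == "FP")
    s <- meta$s[idx]
    phi <- phiFun(s)
    act <- phi > 0
    if (any(act)) {
      ia <- idx[act]
      sa <- s[act]
      L <- config$lengths_m[["FP"]]
      ctr_x <- config$junction_offset_m * .smoothstep(sa / L)
      lat <- cbind(mesh$nodes[ia, 1] - ctr_x, mesh$nodes[ia, 2])
      scale <- 1 + eps * q * phi[act]
      pos[ia, 1] <- ctr_x + scale * lat[, 1]
      pos[ia, 2] <- scale * lat[, 2]
      wallv <- eps * qd * phi[act]
      vel[ia, 1] <- vel[ia, 1] + wallv * lat[, 1]
      vel[ia, 2] <- vel[ia, 2] + wallv * lat[, 2]
    }
  }

  fieldFrame(mesh, t, vel, prs, positions = pos)
}

#' Generate a synthetic rigid or moving-wall field series
#'
#' Builds one cardiac cycle of analytic velocity/pressure fields on the
#' idealized junction: per-branch Poiseuille profiles carrying the
#' instantaneous branch flows (outlets split `lpa_fraction` /
#' `1 - lpa_fraction` of the total), blended smoothly across the junction
#' box, with per-branch linear pressure drops consistent with Poiseuille
#' resistance. In `moving` mode the FP arm wall moves as prescribed by the
#' configuration and the outlet flows are reduced by the analytic cavity
#' volume rate so that global mass balance holds exactly at the caps.
#'
#' @param mesh Mesh from [buildIdealizedTcpc()].
#' @param config The [syntheticConfig()] used to build the mesh.
#' @param mode `"rigid"` or `"moving"`.
#' @param constants [physicalConstants()] (viscosity sets the synthetic
#'   pressure scale).
#' @return A periodic [fieldSeries()] covering one cycle.
#' @export
makeFieldSeries <- function(mesh, config, mode = c("rigid", "moving"),
                            constants = physicalConstants(
                              cycle_period = config$cycle_period)) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "tcpc_mesh"), !is.null(mesh$branch_info))
  nf <- max(2L, round(config$cycle_period / config$frame_interval))
  times <- seq(0, config$cycle_period, length.out = nf + 1)
  frames <- lapply(times, function(t) .synthFrame(mesh, config, t, mode, constants))
  fieldSeries(mesh, frames, config$cycle_period, periodic = TRUE,
              periodic_tol = 1e-6)
}

#' Steady Poiseuille pipe fixture
#'
#' A straight circular pipe carrying steady flow `Q` with the exact parabolic
#' velocity profile and the linear pressure field
#' \eqn{\Delta P = 8 \mu L Q / (\pi R^4)} evaluated at the nodes. Serves as
#' the analytic oracle for fluxes, pressure drop, power loss
#' (\eqn{\Delta P \cdot Q}) and particle transit times (\eqn{L/u(r)}).
#'
#' @param radius_cm Pipe radius in cm.
#' @param length_cm Pipe length in cm.
#' @param flow_ml_s Steady flow rate in mL/s.
#' @param constants [physicalConstants()].
#' @param edge_mm Mesh edge length in mm.
#' @return A steady two-frame periodic [fieldSeries()] whose mesh has `FP`
#'   inlet and `LPA` outlet caps. The analytic pressure drop (Pa) is attached
#'   as the `delta_p` element, the flow (m^3/s) as `flow`.
#' @examples
#' fx <- poiseuilleFixture(0.5, 5, 10, edge_mm = 2)
#' fx$delta_p  # 8 mu L Q / (pi R^4)
#' @export
poiseuilleFixture <- function(radius_cm = 0.5, length_cm = 5, flow_ml_s = 10,
                              constants = physicalConstants(), edge_mm = 2) {
  stopifnot(radius_cm > 0, length_cm > 0, flow_ml_s > 0)
  mesh <- buildPipeMesh(radius_cm, length_cm, edge_mm)
  R <- mesh$pipe$radius
  L <- mesh$pipe$length
  Q <- flow_ml_s * 1e-6
  mu <- constants$dynamic_viscosity
  dP <- 8 * mu * L * Q / (pi * R^4)
  rho2 <- (mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2) / R^2
  vz <- 2 * Q / (pi * R^2) * (1 - rho2)
  vel <- cbind(0, 0, vz)
  prs <- dP * (1 - mesh$nodes[, 3] / L)
  T_ <- constants$cycle_period
  frames <- list(fieldFrame(mesh, 0, vel, prs),
                 fieldFrame(mesh, T_, vel, prs))
  ser <- fieldSeries(mesh, frames, T_, periodic = TRUE)
  ser$delta_p <- dP
  ser$flow <- Q
  ser
}

#' Cutting plane across the Fontan-pathway arm
#'
#' Convenience constructor for the plane normal to the FP axis at a given
#' axial position, accounting for the configured junction offset.
#'
#' @param mesh Mesh from [buildIdealizedTcpc()].
#' @param fraction Axial position as a fraction of the FP arm length.
#' @return `list(point, normal)` suitable for [crossSection()].
#' @export
fpSectionPlane <- function(mesh, fraction = 0.65) {
  cfg <- mesh$config
  L <- cfg$lengths_m[["FP"]]
  s <- fraction * L
  a <- mesh$junction_half_width
  list(point = c(cfg$junction_offset_m * .smoothstep(s / L), 0, -(a + s)),
       normal = c(0, 0, 1))
}
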