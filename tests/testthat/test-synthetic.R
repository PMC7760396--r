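# Synthetic generator: inflows, rigid/moving fields, Poiseuille fixture.

test_that("inflow waveforms have the configured period, mean and shape", {
  cfg <- syntheticConfig()
  wf <- makeInflowWaveforms(cfg)
  expect_equal(max(wf$FP$times), 0.86)
  # periodic: first and last sample equal
  expect_equal(wf$FP$values[1], wf$FP$values[length(wf$FP$values)])
  # trapezoid mean equals the configured mean (cosine harmonics integrate out)
  expect_equal(waveformMean(wf$FP), 30, tolerance = 1e-10)
  expect_equal(waveformMean(wf$SVC), 20, tolerance = 1e-10)
  expect_true(all(wf$FP$values > 0))
  # zero harmonics -> constant waveforms at the means
  cfg0 <- syntheticConfig(inflow = list(FP = list(mean = 12, harmonics = NULL),
                                        SVC = list(mean = 7, harmonics = NULL)))
  wf0 <- makeInflowWaveforms(cfg0)
  expect_equal(unique(wf0$FP$values), 12)
  expect_equal(unique(wf0$SVC$values), 7)
})

test_that("identical configurations generate bit-identical fields", {
  cfg <- syntheticConfig(edge_length = 5, frame_interval = 0.86 / 4)
  m1 <- buildIdealizedTcpc(cfg)
  m2 <- buildIdealizedTcpc(cfg)
  s1 <- makeFieldSeries(m1, cfg, "moving")
  s2 <- makeFieldSeries(m2, cfg, "moving")
  for (i in seq_along(s1$frames)) {
    expect_identical(s1$frames[[i]]$velocity, s2$frames[[i]]$velocity)
    expect_identical(s1$frames[[i]]$positions, s2$frames[[i]]$positions)
    expect_identical(s1$frames[[i]]$pressure, s2$frames[[i]]$pressure)
  }
})

test_that("rigid series closes mass at every frame", {
  nf <- netFlowWaveform(tcpcRigid())
  qbar <- 50  # mean total inflow, mL/s
  expect_lt(max(abs(nf$values)), 0.01 * qbar)
})

test_that("moving series net flow matches the analytic dV/dt within 1%", {
  # steady inflow isolates the wall-motion signal; finer mesh keeps the
  # boundary-flux discretization error below the tolerance
  cfg <- syntheticConfig(edge_length = 1, wall_amplitude = 0.1,
                         frame_interval = 0.86 / 8,
                         inflow = list(FP = list(mean = 5, harmonics = NULL),
                                       SVC = list(mean = 3, harmonics = NULL)))
  mesh <- buildIdealizedTcpc(cfg)
  ser <- makeFieldSeries(mesh, cfg, "moving")
  nf <- netFlowWaveform(ser)
  dv <- movingVolumeRate(cfg, nf$times)
  expect_lt(max(abs(nf$values - dv)), 0.01 * max(abs(dv)))
})

test_that("zero wall amplitude reduces moving mode to the rigid fields", {
  cfg <- syntheticConfig(edge_length = 5, wall_amplitude = 0,
                         frame_interval = 0.86 / 4)
  mesh <- buildIdealizedTcpc(cfg)
  rig <- makeFieldSeries(mesh, cfg, "rigid")
  mov <- makeFieldSeries(mesh, cfg, "moving")
  for (i in seq_along(rig$frames)) {
    expect_identical(mov$frames[[i]]$positions, rig$frames[[i]]$positions)
    expect_identical(mov$frames[[i]]$velocity, rig$frames[[i]]$velocity)
    expect_identical(mov$frames[[i]]$pressure, rig$frames[[i]]$pressure)
  }
})

test_that("mesh motion volume matches the closed-form volume change", {
  cfg <- syntheticConfig(edge_length = 2, wall_amplitude = 0.1,
                         frame_interval = 0.86 / 8)
  mesh <- buildIdealizedTcpc(cfg)
  ser <- makeFieldSeries(mesh, cfg, "moving")
  v0 <- meshVolume(mesh)
  dv_mesh <- vapply(ser$frames, function(f) {
    (meshVolume(mesh, f$positions) - v0) * 1e6
  }, numeric(1))
  dv_exact <- movingVolumeChange(cfg, ser$times)
  expect_equal(dv_mesh, dv_exact, tolerance = 0.01)
})

test_that("Poiseuille fixture carries the exact closed forms at the nodes", {
  fx <- pipeSmall()
  mesh <- fx$mesh
  R <- mesh$pipe$radius
  L <- mesh$pipe$length
  Q <- fx$flow
  mu <- physicalConstants()$dynamic_viscosity
  expect_equal(fx$delta_p, 8 * mu * L * Q / (pi * R^4), tolerance = 1e-15)
  fr <- fx$frames[[1]]
  r2 <- mesh$nodes[, 1]^2 + mesh$nodes[, 2]^2
  expect_equal(fr$velocity[, 3], 2 * Q / (pi * R^2) * (1 - r2 / R^2),
               tolerance = 1e-12)
  expect_equal(fr$pressure, fx$delta_p * (1 - mesh$nodes[, 3] / L),
               tolerance = 1e-12)
  # doubling the flow doubles the pressure drop
  fx2 <- poiseuilleFixture(0.5, 3, 20, edge_mm = 2)
  expect_equal(fx2$delta_p, 2 * fx$delta_p, tolerance = 1e-12)
})

test_that("fixture power loss equals the analytic dissipation within 1%", {
  fx <- pipeFine()
  pl <- powerLoss(fx$frames[[1]])
  expect_equal(pl, mWFromW(fx$delta_p * fx$flow), tolerance = 0.01)
})
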