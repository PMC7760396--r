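# Deformation index, area/volume waveforms, compliance estimation.

test_that("deformation index reproduces the reference arithmetic", {
  # mean 3.74 cm^2, range 0.20 cm^2 -> 5.3 % to one decimal
  a1 <- scalarWaveform(0:9, 3.74 + 0.10 * rep(c(-1, 1), 5), "cm^2")
  expect_equal(round(deformationIndex(a1)$DI, 1), 5.3)
  # phase-contrast reference: mean 6.81, range 0.37 -> 5.4 %
  a2 <- scalarWaveform(0:9, 6.81 + 0.185 * rep(c(-1, 1), 5), "cm^2")
  expect_equal(round(deformationIndex(a2)$DI, 1), 5.4)
  # constant waveform -> 0 %
  a3 <- scalarWaveform(0:4, rep(2.5, 5), "cm^2")
  expect_equal(deformationIndex(a3)$DI, 0)
  # densely sampled sinusoid: DI -> 2 * amplitude fraction * 100
  tt <- seq(0, 0.86, length.out = 2001)
  a4 <- scalarWaveform(tt, 2 * (1 + 0.05 * sin(2 * pi * tt / 0.86)), "cm^2")
  expect_equal(round(deformationIndex(a4)$DI, 1), 10.0)
})

test_that("deformation index is scale invariant and validates inputs", {
  tt <- seq(0, 1, by = 0.1)
  a <- scalarWaveform(tt, 3 + sin(2 * pi * tt), "cm^2")
  di1 <- deformationIndex(a)
  for (k in c(0.1, 2, 17)) {
    ak <- scalarWaveform(tt, k * a$values, "cm^2")
    expect_equal(deformationIndex(ak)$DI, di1$DI, tolerance = 1e-12)
  }
  expect_true(di1$A_min <= di1$A_mean && di1$A_mean <= di1$A_max)
  expect_error(deformationIndex(scalarWaveform(1, -2, "cm^2")), "positive")
})

test_that("area waveform is constant on rigid series and scales as prescribed on moving walls", {
  cfg <- tcpcConfig()
  mesh <- tcpcMeshFix()
  plane <- fpSectionPlane(mesh, 0.65)
  aw_r <- areaWaveform(tcpcRigid(), plane, "FP")
  expect_lt(waveformRange(aw_r) / mean(aw_r$values), 1e-12)

  # moving wall: area range over mean matches (1+e)^2 - (1-e)^2 over 1+e^2/2.
  # A station-aligned cut (0.65 L is a mesh station at this resolution) makes
  # the radial scaling of the cut polygon exact.
  eps <- 0.1
  cfg_m <- syntheticConfig(edge_length = 1.5, wall_amplitude = eps)
  mesh_m <- buildIdealizedTcpc(cfg_m)
  ser_m <- makeFieldSeries(mesh_m, cfg_m, "moving")
  aw_m <- areaWaveform(ser_m, fpSectionPlane(mesh_m, 0.65), "FP")
  expect_equal(waveformRange(aw_m) / mean(aw_m$values),
               ((1 + eps)^2 - (1 - eps)^2) / (1 + eps^2 / 2),
               tolerance = 0.02)

  # single-frame series -> length-1 waveform
  one <- fieldSeries(mesh, tcpcRigid()$frames[1], 0.86, periodic = FALSE)
  expect_length(areaWaveform(one, plane, "FP")$values, 1)
})

test_that("volume waveform integrates net flow by the trapezoidal rule", {
  tt <- seq(0, 0.86, length.out = 400)
  zero <- scalarWaveform(tt, numeric(length(tt)), "mL/s")
  expect_equal(unique(volumeWaveform(zero, 62.25)$values), 62.25)

  # cosine net flow -> sine volume, O(dt^2)
  Tc <- 0.86
  q0 <- 10
  qn <- scalarWaveform(tt, q0 * cos(2 * pi * tt / Tc), "mL/s")
  v <- volumeWaveform(qn, 60)
  v_exact <- 60 + q0 * Tc / (2 * pi) * sin(2 * pi * tt / Tc)
  expect_equal(v$values, v_exact, tolerance = 1e-4)
  # whole-cycle integral of a periodic zero-mean flow returns to V0
  expect_equal(v$values[length(tt)], 60, tolerance = 1e-6)

  # linearity
  qn2 <- scalarWaveform(tt, 2 * qn$values, "mL/s")
  expect_equal(volumeWaveform(qn2, 0)$values, 2 * volumeWaveform(qn, 0)$values,
               tolerance = 1e-12)
})

test_that("volume extrema and pressure range give the reference compliance", {
  # volume waveform with the reference extrema 62.49 / 64.46 cm^3
  tt <- c(0, 0.3, 0.45, 0.86)
  vol <- scalarWaveform(tt, c(63.0, 62.49, 64.46, 63.0), "mL")
  expect_equal(waveformRange(vol), 1.97, tolerance = 1e-12)
  prs <- scalarWaveform(tt, c(0.5, 0.07, 0.87, 0.5), "mmHg")
  ce <- estimateCompliance(vol, prs)
  expect_equal(ce$dP_max, 0.8, tolerance = 1e-12)
  expect_equal(round(ce$C, 2), 2.46)
  # constant volume -> C = 0; flat pressure -> error
  flat <- scalarWaveform(tt, rep(63, 4), "mL")
  expect_equal(estimateCompliance(flat, prs)$C, 0)
  expect_error(estimateCompliance(vol, scalarWaveform(tt, rep(1, 4), "mmHg")),
               "pressure range")
})

test_that("compliance estimator recovers the configured lumped compliance", {
  om <- 2 * pi / 0.86
  m <- lumpedTcpcModel(C = 2.00,
                       Q_FP = function(t) 30 * (1 + 0.4 * cos(om * t)),
                       Q_SVC = 20)
  sol <- simulateLumped(m, dt = 0.86 / 400, n_cycles = 25)
  ce <- estimateCompliance(sol$volume, sol$pressure)
  expect_equal(ce$C, 2.00, tolerance = 1e-3)
})

test_that("volume-averaged pressure responds to the branch pressure scale", {
  ser <- tcpcRigid()
  pw <- volumeAveragedPressure(ser)
  expect_length(pw$values, length(ser$frames))
  expect_true(all(is.finite(pw$values)))
  expect_equal(pw$unit, "mmHg")
})
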