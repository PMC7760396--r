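# Lumped compliant-chamber surrogate and stiffness calibration.

test_that("constant inflow gives the exact algebraic steady state", {
  m <- lumpedTcpcModel(C = 2.46, R_LPA = 0.3, R_RPA = 0.6, P_out = 10,
                       Q_FP = 30, Q_SVC = 20)
  sol <- simulateLumped(m, n_cycles = 40)
  Rp <- 1 / (1 / 0.3 + 1 / 0.6)
  expect_equal(waveformMean(sol$pressure), 10 + 50 * Rp, tolerance = 1e-6)
  # rigid limit: exact algebraic balance at every sample
  m0 <- lumpedTcpcModel(C = 0, R_LPA = 0.3, R_RPA = 0.6, P_out = 10,
                        Q_FP = 30, Q_SVC = 20)
  sol0 <- simulateLumped(m0, n_cycles = 2)
  expect_equal(sol0$pressure$values, rep(10 + 50 * Rp, length(sol0$times)),
               tolerance = 1e-12)
})

test_that("sinusoidal forcing matches the linear frequency response within 1%", {
  om <- 2 * pi / 0.86
  amp <- 0.4 * 30
  m <- lumpedTcpcModel(C = 2.46, R_LPA = 0.3, R_RPA = 0.3, P_out = 10,
                       Q_FP = function(t) 30 * (1 + 0.4 * sin(om * t)),
                       Q_SVC = 20)
  sol <- simulateLumped(m, dt = 0.86 / 1000, n_cycles = 30)
  Rp <- 0.15
  expect_true(sol$converged)
  expect_equal(waveformRange(sol$pressure) / 2,
               amp * Rp / sqrt(1 + (om * Rp * m$C)^2), tolerance = 0.01)
  # rigid case tracks the inflow algebraically
  m0 <- lumpedTcpcModel(C = 0, R_LPA = 0.3, R_RPA = 0.3, P_out = 10,
                        Q_FP = m$Q_FP, Q_SVC = 20)
  sol0 <- simulateLumped(m0, dt = 0.86 / 1000, n_cycles = 2)
  expect_equal(sol0$pressure$values,
               10 + (m$Q_FP(sol0$times) + 20) * Rp, tolerance = 1e-12)
})

test_that("time averages are compliance-independent while fluctuations shrink", {
  om <- 2 * pi / 0.86
  m <- lumpedTcpcModel(C = 2.46, R_LPA = 0.25, R_RPA = 0.40, P_out = 9,
                       Q_FP = function(t) 30 * (1 + 0.35 * cos(om * t) +
                                                  0.1 * cos(2 * om * t + 0.7)),
                       Q_SVC = function(t) 20 * (1 + 0.3 * cos(om * t + 0.4)))
  cmp <- compareRigidCompliant(m, dt = 0.86 / 500, n_cycles = 40)
  tab <- cmp$table
  dp <- tab[tab$quantity == "dp_mean", ]
  expect_lt(abs(dp$rigid - dp$compliant) / dp$rigid, 0.005)
  rng <- tab[tab$quantity == "dp_range", ]
  expect_lt(rng$compliant, rng$rigid)
  # flow split equals the resistance ratio, independent of C
  fr <- tab[tab$quantity == "lpa_fraction_mean", ]
  expect_equal(fr$rigid, 0.40 / 0.65, tolerance = 0.005)
  expect_equal(fr$compliant, 0.40 / 0.65, tolerance = 0.005)
})

test_that("pressure fluctuation amplitude is non-increasing in compliance", {
  om <- 2 * pi / 0.86
  qf <- function(t) 30 * (1 + 0.4 * sin(om * t))
  amps <- vapply(c(0, 0.5, 1.5, 2.46, 5), function(C) {
    m <- lumpedTcpcModel(C = C, Q_FP = qf, Q_SVC = 20)
    waveformRange(simulateLumped(m, dt = 0.86 / 500, n_cycles = 30)$pressure)
  }, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("cyclic volume is conserved at periodic steady state", {
  om <- 2 * pi / 0.86
  m <- lumpedTcpcModel(C = 2.46, Q_FP = function(t) 30 * (1 + 0.4 * sin(om * t)),
                       Q_SVC = 20)
  sol <- simulateLumped(m, dt = 0.86 / 500, n_cycles = 40)
  qnet <- m$Q_FP(sol$times) + m$Q_SVC(sol$times) -
    sol$Q_LPA$values - sol$Q_RPA$values
  cyc <- pracma::trapz(sol$times, qnet)
  expect_lt(abs(cyc), 1e-6 * pracma::trapz(sol$times, m$Q_FP(sol$times)))
})

test_that("stiffness calibration brackets and converges", {
  # target at the bracket edge returns the bound
  fwd <- function(k) 10 / k
  expect_equal(calibrateStiffness(fwd(0.5), fwd, c(0.5, 100)), 0.5)
  # closed-form forward model
  expect_equal(calibrateStiffness(5.3, fwd, c(0.5, 100)), 10 / 5.3,
               tolerance = 1e-3 * 10 / 5.3)
  # unattainable target -> error listing the range
  expect_error(calibrateStiffness(1000, fwd, c(0.5, 100)), "range")
  expect_error(calibrateStiffness(5.3, function(k) k, c(0.5, 100)),
               "monotone")
})

test_that("calibrated stiffness reproduces the target DI end-to-end", {
  target <- 5.3
  fwd <- function(E) amplitudeToDI(stiffnessToAmplitude(E))
  E_star <- calibrateStiffness(target, fwd, c(0.01, 1))
  eps <- stiffnessToAmplitude(E_star)
  # replay through mesh, area waveform and deformation index
  cfg <- syntheticConfig(edge_length = 1.5, wall_amplitude = eps)
  mesh <- buildIdealizedTcpc(cfg)
  ser <- makeFieldSeries(mesh, cfg, "moving")
  di <- deformationIndex(areaWaveform(ser, fpSectionPlane(mesh, 0.65), "FP"))
  expect_lt(abs(di$DI - target), 0.2)
})
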