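# Lagrangian seeding, advection, residence statistics and HFD.

test_that("seeding protocol arithmetic matches the reference counts", {
  # 700 seeds/event at 1 ms intervals over one 0.86 s cycle -> 602,000
  proto <- seedingProtocol(interval = 0.001, duration = 0.86)
  events <- seq(0, proto$duration - proto$interval / 2, by = proto$interval)
  expect_length(events, 860)
  expect_equal(860 * 700, 602000)

  # small instantiation on the pipe follows the same arithmetic
  fx <- pipeSmall()
  p2 <- seedingProtocol(interval = 0.01, duration = 0.1, seeds_per_event = 3,
                        horizon_cycles = 1)
  ens <- seedParticles(fx, p2)
  expect_equal(nrow(ens$particles), 10 * 3)
  # duration == interval -> single event
  p1 <- seedingProtocol(interval = 0.01, duration = 0.01, seeds_per_event = 5)
  expect_equal(nrow(seedParticles(fx, p1)$particles), 5)
})

test_that("every seed point is inside the domain at its seed time", {
  fx <- pipeSmall()
  ens <- seedParticles(fx, seedingProtocol(interval = 0.05, duration = 0.2))
  fr <- fx$frames[[1]]
  pts <- as.matrix(ens$particles[, c("x0", "y0", "z0")])
  idx <- seq(1, nrow(pts), length.out = min(25, nrow(pts)))
  for (i in idx) {
    expect_false(is.null(locateCell(pts[i, ], fr, method = "scan")))
  }
})

test_that("uniform flow gives exact exit times", {
  U <- 0.05
  ser <- plugFlowSeries(U)
  L <- ser$mesh$pipe$length
  proto <- seedingProtocol(interval = 0.01, duration = 0.01, jitter = 0,
                           horizon_cycles = 3)
  ens <- advectParticles(seedParticles(ser, proto), ser, substep = 1e-3)
  df <- ens$particles
  expect_true(all(df$state == "exited"))
  expect_true(all(df$exit_patch == "LPA"))
  expect_equal(df$exit_time, (L - df$z0) / U, tolerance = 1e-8)
})

test_that("rigid-body rotation conserves particle radius", {
  mesh <- pipeSmall()$mesh
  n <- nrow(mesh$nodes)
  om <- 2 * pi  # one revolution per second
  vel <- cbind(-om * mesh$nodes[, 2], om * mesh$nodes[, 1], 0)
  ser <- fieldSeries(mesh, list(fieldFrame(mesh, 0, vel, numeric(n)),
                                fieldFrame(mesh, 1, vel, numeric(n))),
                     1, periodic = TRUE)
  r0 <- 0.6 * mesh$pipe$radius
  seeds <- matrix(c(r0, 0, mesh$pipe$length / 2), 1)
  res <- tcpcflow:::cpp_advect(
    mesh$tets - 1L, tcpcflow:::neighbors0(mesh), mesh$nodes,
    list(), list(vel, vel), c(0, 1), 1, FALSE,
    cbind(matrix(0, 0, 7), integer(0)),
    seeds, 0, 5e-4, 1, 1e-10, FALSE
  )
  r1 <- sqrt(res$final_pos[1]^2 + res$final_pos[2]^2)
  expect_equal(r1, r0, tolerance = 1e-6)
})

test_that("Poiseuille transit times match L/u(r) within 0.1%", {
  fx <- pipeTransit()
  mesh <- fx$mesh
  proto <- seedingProtocol(interval = 0.01, duration = 0.01, jitter = 0,
                           horizon_cycles = 40)
  ens <- advectParticles(seedParticles(fx, proto), fx, substep = 2e-3)
  df <- ens$particles
  expect_true(all(df$state == "exited"))
  u <- 2 * fx$flow / (pi * mesh$pipe$radius^2) *
    (1 - (df$x0^2 + df$y0^2) / mesh$pipe$radius^2)
  expected <- (mesh$pipe$length - df$z0) / u
  expect_lt(max(abs(df$residence_time - expected) / expected), 1e-3)
})

test_that("halving the substep changes exit times by less than 1e-4 relative", {
  fx <- pipeTransit()
  proto <- seedingProtocol(interval = 0.01, duration = 0.01, jitter = 0.01,
                           seeds_per_event = 10, horizon_cycles = 40)
  e1 <- advectParticles(seedParticles(fx, proto), fx, substep = 2e-3)
  e2 <- advectParticles(seedParticles(fx, proto), fx, substep = 1e-3)
  expect_identical(e1$particles[, c("x0", "y0", "z0")],
                   e2$particles[, c("x0", "y0", "z0")])
  rel <- abs(e1$particles$exit_time - e2$particles$exit_time) /
    e2$particles$exit_time
  expect_lt(max(rel), 1e-4)
})

test_that("walking and exhaustive locators track particle-for-particle", {
  tiny <- tcpcTiny()
  ser <- makeFieldSeries(tiny$mesh, tiny$config, "rigid")
  proto <- seedingProtocol(interval = 0.86 / 4, duration = 0.86,
                           seeds_per_event = 6, horizon_cycles = 3)
  walk <- advectParticles(seedParticles(ser, proto), ser,
                          substep = 5e-3, locator = "walk")
  scan <- advectParticles(seedParticles(ser, proto), ser,
                          substep = 5e-3, locator = "scan")
  expect_identical(walk$particles$state, scan$particles$state)
  expect_identical(walk$particles$exit_patch, scan$particles$exit_patch)
  ok <- walk$particles$state == "exited"
  expect_equal(walk$particles$exit_time[ok], scan$particles$exit_time[ok],
               tolerance = 1e-8)
})

test_that("particle accounting is conserved and substep validation works", {
  ser <- tcpcRigid()
  proto <- seedingProtocol(interval = 0.86 / 10, duration = 0.86,
                           seeds_per_event = 5, horizon_cycles = 2)
  ens <- advectParticles(seedParticles(ser, proto), ser, substep = 2e-3)
  w <- suppressWarnings(residenceStats(ens))
  expect_equal(sum(w$counts[c("exited", "stranded", "active")]),
               unname(w$counts["seeded"]))
  expect_error(advectParticles(seedParticles(ser, proto), ser, substep = 1),
               "substep")
})

test_that("washout statistics follow their definitions", {
  # constructed exit times 1..100 s, seeds at t = 0 -> W95 = 95 s
  ens <- manualEnsemble(seed_time = rep(0, 100),
                        state = rep("exited", 100),
                        exit_patch = rep(c("LPA", "RPA"), 50),
                        exit_time = as.numeric(1:100))
  w <- residenceStats(ens, bin_width = 5)
  expect_equal(w$W95, 95)
  expect_equal(w$W95_cycles, 95 / 0.86)
  expect_equal(sum(w$histogram$counts), 100)

  # 10% stranded -> washout flagged with the achieved fraction
  st <- rep(c("exited", "stranded"), c(90, 10))
  ens2 <- manualEnsemble(seed_time = rep(0, 100), state = st,
                         exit_patch = ifelse(st == "exited", "LPA", NA),
                         exit_time = ifelse(st == "exited", 1:100, NA))
  expect_warning(w2 <- residenceStats(ens2), "90.0%")
  expect_true(is.na(w2$W95))
  expect_equal(w2$achieved_fraction, 0.9)
})

test_that("plug-flow washout completes one transit after seeding ends", {
  U <- 0.05
  ser <- plugFlowSeries(U)
  L <- ser$mesh$pipe$length
  proto <- seedingProtocol(interval = 0.02, duration = 0.2, jitter = 0,
                           horizon_cycles = 3)
  ens <- advectParticles(seedParticles(ser, proto), ser, substep = 1e-3)
  w <- residenceStats(ens)
  last_seed <- max(ens$particles$seed_time)
  transit <- L / U
  expect_lt(abs(w$W95 - (last_seed + transit)), transit * 0.1)
})

test_that("hepatic flow distribution counts fates correctly", {
  # all particles to the LPA -> 100 %
  e1 <- manualEnsemble(rep(0, 10), rep("exited", 10), rep("LPA", 10),
                       rep(1, 10))
  expect_equal(hfd(e1)$hfd_lpa, 100)
  # 19 of 100 PA-exited to the LPA -> 19 %
  patches <- rep(c("LPA", "RPA"), c(19, 81))
  e2 <- manualEnsemble(rep(0, 100), rep("exited", 100), patches,
                       rep(1, 100))
  h2 <- hfd(e2)
  expect_equal(h2$hfd_lpa, 19)
  expect_equal(h2$hfd_lpa + h2$hfd_rpa, 100)
  # caval backflow exits excluded from the denominator
  patches3 <- c(rep("LPA", 5), rep("RPA", 5), rep("FP", 10))
  e3 <- manualEnsemble(rep(0, 20), rep("exited", 20), patches3, rep(1, 20))
  expect_equal(hfd(e3)$n_pa, 10)
  expect_equal(hfd(e3)$hfd_lpa, 50)
  # no PA exits -> error
  e4 <- manualEnsemble(0, "exited", "SVC", 1)
  expect_error(hfd(e4), "pulmonary")
})

test_that("the symmetric junction splits hepatic flow 50/50 within 3 sigma", {
  ser <- tcpcRigid()
  proto <- seedingProtocol(interval = 0.86 / 20, duration = 0.86,
                           seeds_per_event = 12, horizon_cycles = 5)
  ens <- advectParticles(seedParticles(ser, proto), ser, substep = 2e-3)
  h <- hfd(ens)
  tol3 <- 3 * sqrt(0.25 / h$n_pa) * 100
  expect_lt(abs(h$hfd_lpa - 50), tol3)
  expect_equal(h$hfd_lpa + h$hfd_rpa, 100)
  # instantaneous series bounded in [0, 100]
  expect_true(all(h$instantaneous$values >= 0 & h$instantaneous$values <= 100))
})

test_that("moving-wall advection conserves particles without tunneling", {
  ser <- tcpcMoving()
  proto <- seedingProtocol(interval = 0.86 / 10, duration = 0.86,
                           seeds_per_event = 6, horizon_cycles = 5)
  ens <- advectParticles(seedParticles(ser, proto), ser, substep = 2e-3)
  df <- ens$particles
  expect_equal(nrow(df), 60)
  expect_true(all(df$state %in% c("active", "exited", "stranded")))
  # exits must be through registered caps with consistent residence times
  ex <- df[df$state == "exited", ]
  expect_true(all(ex$exit_patch %in% c("FP", "SVC", "LPA", "RPA")))
  expect_true(all(ex$residence_time >= 0))
  expect_gt(nrow(ex), 0.8 * nrow(df))
})
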