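# Shared fixtures, built once per test run and cached.
#
# Mesh resolutions are chosen so that the discretization error of each
# analytic comparison sits comfortably inside the asserted tolerance
# (boundary-flux and power-loss errors scale as O(h^2); see the methods
# vignette for the convergence measurements behind these choices).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# fine straight pipe: flux / power-loss oracles at the 1 % level
pipeFine <- function() {
  fixture("pipe_fine", function() poiseuilleFixture(0.5, 2, 10, edge_mm = 0.5))
}

# small straight pipe (< 5000 cells): exhaustive-search oracles
pipeSmall <- function() {
  fixture("pipe_small", function() poiseuilleFixture(0.5, 3, 10, edge_mm = 2))
}

# medium pipe for particle transit tests
pipeTransit <- function() {
  fixture("pipe_transit", function() poiseuilleFixture(0.5, 3, 10, edge_mm = 1.25))
}

# default-geometry junction at the desk-scale test resolution
tcpcConfig <- function(...) syntheticConfig(edge_length = 2.5, ...)

tcpcMeshFix <- function() {
  fixture("tcpc_mesh", function() buildIdealizedTcpc(tcpcConfig()))
}

tcpcRigid <- function() {
  fixture("tcpc_rigid", function() makeFieldSeries(tcpcMeshFix(), tcpcConfig(), "rigid"))
}

tcpcMoving <- function(wall_amplitude = 0.05) {
  fixture(paste0("tcpc_moving_", wall_amplitude), function() {
    makeFieldSeries(tcpcMeshFix(), tcpcConfig(wall_amplitude = wall_amplitude),
                    "moving")
  })
}

# small junction (< 5000 cells) for locator/tracker oracle equivalence
tcpcTiny <- function() {
  fixture("tcpc_tiny", function() {
    cfg <- syntheticConfig(edge_length = 5.5, frame_interval = 0.86 / 8)
    list(config = cfg, mesh = buildIdealizedTcpc(cfg))
  })
}

# hand-built particle ensemble with prescribed fates (for the statistics
# operations, which only consume the fate table)
manualEnsemble <- function(seed_time, state, exit_patch, exit_time,
                           period = 0.86) {
  n <- length(seed_time)
  df <- data.frame(
    id = seq_len(n), seed_time = seed_time,
    x0 = 0, y0 = 0, z0 = 0,
    state = state, exit_patch = exit_patch, exit_time = exit_time,
    residence_time = exit_time - seed_time,
    stringsAsFactors = FALSE
  )
  structure(list(particles = df,
                 protocol = seedingProtocol(interval = 1, duration = 1),
                 period = period, advected = TRUE),
            class = "particle_ensemble")
}

# uniform plug-flow series on the small pipe (exact transit oracle)
plugFlowSeries <- function(U = 0.05) {
  fixture(paste0("plug_", U), function() {
    mesh <- pipeSmall()$mesh
    n <- nrow(mesh$nodes)
    vel <- cbind(0, 0, rep(U, n))
    frames <- list(fieldFrame(mesh, 0, vel, numeric(n)),
                   fieldFrame(mesh, 0.86, vel, numeric(n)))
    fieldSeries(mesh, frames, 0.86, periodic = TRUE)
  })
}
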