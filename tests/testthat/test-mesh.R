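# Mesh construction, validity and geometric queries.

test_that("idealized junction mesh is watertight, labeled and cap-planar", {
  mesh <- tcpcMeshFix()
  expect_s3_class(mesh, "tcpc_mesh")
  expect_setequal(unique(mesh$facet_patch),
                  c("FP", "SVC", "LPA", "RPA", "WALL"))
  expect_equal(sort(capNames(mesh)), sort(c("FP", "SVC", "LPA", "RPA")))
  expect_true(validateMesh(mesh))
  expect_true(all(tetVolumes(mesh$tets, mesh$nodes) > 0))
})

test_that("halving the edge length increases the cell count", {
  coarse <- buildIdealizedTcpc(syntheticConfig(edge_length = 5))
  fine <- buildIdealizedTcpc(syntheticConfig(edge_length = 2.5))
  expect_gt(nrow(fine$tets), nrow(coarse$tets))
})

test_that("zero offset with equal PA radii gives an LPA/RPA mirror-symmetric mesh", {
  mesh <- buildIdealizedTcpc(syntheticConfig(edge_length = 5))
  mirrored <- mesh$nodes
  mirrored[, 1] <- -mirrored[, 1]
  # every mirrored node must coincide with an existing node
  key <- function(m) paste(round(m[, 1], 12), round(m[, 2], 12), round(m[, 3], 12))
  expect_true(all(key(mirrored) %in% key(mesh$nodes)))
})

test_that("an over-large junction offset is rejected as non-manifold", {
  expect_error(
    buildIdealizedTcpc(syntheticConfig(junction_offset = 2.5, edge_length = 5)),
    "non-manifold"
  )
})

test_that("mesh build is deterministic for a fixed configuration", {
  a <- buildIdealizedTcpc(syntheticConfig(edge_length = 5))
  b <- buildIdealizedTcpc(syntheticConfig(edge_length = 5))
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$tets, b$tets)
  expect_identical(a$facet_patch, b$facet_patch)
})

test_that("locateCell finds centroids, vertices and rejects outside points", {
  fx <- pipeSmall()
  fr <- fx$frames[[1]]
  mesh <- fx$mesh
  # tetrahedron centroid -> that cell with weights 1/4 each
  ci <- 17L
  ctr <- colMeans(mesh$nodes[mesh$tets[ci, ], ])
  loc <- locateCell(ctr, fr)
  expect_equal(loc$cell, ci)
  expect_equal(loc$weights, rep(0.25, 4), tolerance = 1e-12)
  # a mesh vertex -> weight 1 on that vertex, lowest incident cell index
  v <- mesh$tets[40, 2]
  locv <- locateCell(mesh$nodes[v, ], fr)
  incident <- which(rowSums(matrix(mesh$tets %in% v, ncol = 4)) > 0)
  expect_equal(locv$cell, min(incident))
  expect_equal(max(locv$weights), 1, tolerance = 1e-9)
  # far outside
  expect_null(locateCell(c(1, 1, 1), fr))
})

test_that("walking locator agrees with the exhaustive scan", {
  fx <- pipeSmall()
  fr <- fx$frames[[1]]
  mesh <- fx$mesh
  set.seed(42)
  R <- mesh$pipe$radius
  L <- mesh$pipe$length
  pts <- cbind(runif(50, -R, R), runif(50, -R, R), runif(50, -0.2 * L, 1.2 * L))
  for (i in seq_len(nrow(pts))) {
    a <- locateCell(pts[i, ], fr, method = "scan")
    b <- locateCell(pts[i, ], fr, method = "walk")
    if (is.null(a)) {
      expect_null(b)
    } else {
      # both must contain the point (cells may differ only on shared faces)
      expect_false(is.null(b))
      wa <- tcpcflow:::.baryAll(mesh$tets[b$cell, , drop = FALSE],
                                fr$positions, pts[i, ])
      expect_true(all(wa >= -1e-9))
    }
  }
})

test_that("cross-section of a cylinder matches the circle area", {
  fx <- pipeFine()
  cs <- crossSection(fx$frames[[1]],
                     list(point = c(0, 0, 0.01), normal = c(0, 0, 1)))
  expect_equal(cs$area_cm2, pi * 0.5^2, tolerance = 0.01)
})

test_that("cross-section area error decreases monotonically under refinement", {
  errs <- vapply(c(2, 1.5, 1), function(e) {
    fx <- poiseuilleFixture(1.0, 2, 10, edge_mm = e)
    cs <- crossSection(fx$frames[[1]],
                       list(point = c(0, 0, 0.01), normal = c(0, 0, 1)))
    abs(cs$area_cm2 - pi) / pi
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("a plane outside the geometry is an error", {
  fx <- pipeSmall()
  expect_error(
    crossSection(fx$frames[[1]], list(point = c(0, 0, 1), normal = c(0, 0, 1))),
    "misses"
  )
  expect_error(
    crossSection(tcpcRigid()$frames[[1]],
                 list(point = c(0, 0, 1), normal = c(0, 0, 1)), branch = "FP"),
    "misses"
  )
})

test_that("boundary flux recovers plug and Poiseuille flows within 1%", {
  # plug flow through the circular cap (fine mesh: the cap polygon must
  # resolve the circle to within the tolerance)
  fmesh <- pipeFine()$mesh
  plugf <- fieldFrame(fmesh, 0, cbind(0, 0, rep(0.05, nrow(fmesh$nodes))),
                      numeric(nrow(fmesh$nodes)))
  R <- fmesh$pipe$radius
  expect_equal(boundaryFlux(plugf, "LPA"),
               0.05 * pi * R^2 * 1e6, tolerance = 0.01)
  # zero velocity -> exactly zero
  mesh <- pipeSmall()$mesh
  zf <- fieldFrame(mesh, 0, matrix(0, nrow(mesh$nodes), 3),
                   numeric(nrow(mesh$nodes)))
  expect_identical(boundaryFlux(zf, "FP"), 0)
  # Poiseuille profile carries the prescribed flow
  fx <- pipeFine()
  expect_equal(boundaryFlux(fx$frames[[1]], "FP"), 10, tolerance = 0.01)
  expect_equal(boundaryFlux(fx$frames[[1]], "LPA"), 10, tolerance = 0.01)
  expect_error(boundaryFlux(fx$frames[[1]], "SVC"), "unknown patch")
})
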