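# Geometric queries: point location, boundary fluxes, planar cross-sections.

# Barycentric weights of point p in all tets (vectorized Cramer solves).
# Returns n_tet x 4 matrix of weights (rows sum to 1 where det != 0).
.baryAll <- function(tets, pos, p) {
  A <- pos[tets[, 1], , drop = FALSE]
  B <- pos[tets[, 2], , drop = FALSE] - A
  C <- pos[tets[, 3], , drop = FALSE] - A
  D <- pos[tets[, 4], , drop = FALSE] - A
  P <- matrix(p, nrow(tets), 3, byrow = TRUE) - A
  crossM <- function(x, y) {
    cbind(x[, 2] * y[, 3] - x[, 3] * y[, 2],
          x[, 3] * y[, 1] - x[, 1] * y[, 3],
          x[, 1] * y[, 2] - x[, 2] * y[, 1])
  }
  dotM <- function(x, y) rowSums(x * y)
  cd <- crossM(C, D)
  det <- dotM(B, cd)
  w2 <- dotM(P, cd) / det
  w3 <- dotM(B, crossM(P, D)) / det
  w4 <- dotM(B, crossM(C, P)) / det
  cbind(1 - w2 - w3 - w4, w2, w3, w4)
}

#' Locate the cell containing a point
#'
#' Finds the tetrahedron containing `point` in a field frame, together with
#' its four barycentric weights. Two locators are available: a robust
#' exhaustive scan over all cells (the reference), and a neighbor-walking
#' locator seeded by `start_cell` with a scan fallback (used internally by
#' the particle tracker). Points on shared faces or vertices are resolved to
#' the lowest containing cell index.
#'
#' @param point Numeric length-3 position (m).
#' @param frame A [fieldFrame()] (its positions define the cell shapes).
#' @param method `"scan"` (exhaustive, lowest-index tie-break) or `"walk"`.
#' @param start_cell Starting cell for the walking locator.
#' @param tol Barycentric containment tolerance (relative).
#' @return `list(cell, weights)` or `NULL` if the point is outside the mesh.
#' @export
locateCell <- function(point, frame, method = c("scan", "walk"),
                       start_cell = 1L, tol = 1e-10) {
  method <- match.arg(method)
  mesh <- frame$mesh
  if (method == "scan") {
    W <- .baryAll(mesh$tets, frame$positions, point)
    vol <- tetVolumes(mesh$tets, frame$positions)
    if (any(vol <= 0)) stop("degenerate (non-positive volume) cell in frame")
    inside <- which(rowSums(W >= -tol) == 4)
    if (length(inside) == 0) return(NULL)
    cell <- min(inside)
    w <- pmax(unname(W[cell, ]), 0)
    return(list(cell = cell, weights = w / sum(w)))
  }
  res <- cpp_locate_point(mesh$tets - 1L, neighbors0(mesh), frame$positions,
                          as.numeric(point), as.integer(start_cell) - 1L, tol)
  if (res$cell < 0) return(NULL)
  list(cell = res$cell + 1L, weights = res$weights)
}

# 0-based neighbor table with -1 for boundary, cached on the mesh environment
neighbors0 <- function(mesh) {
  nb <- mesh$neighbors
  nb[is.na(nb)] <- 0L
  nb - 1L
}

#' Volumetric flow through a boundary patch
#'
#' Integrates the linearly interpolated velocity over the triangular facets
#' of a cap patch. The sign convention is positive into the domain for inlet
#' patches and positive out of the domain for outlet patches.
#'
#' @param frame A [fieldFrame()].
#' @param patch Patch label (`FP`, `SVC`, `LPA`, `RPA`).
#' @return Flow in mL/s.
#' @export
boundaryFlux <- function(frame, patch) {
  mesh <- frame$mesh
  idx <- patchFacets(mesh, patch)
  f <- mesh$facets[idx, , drop = FALSE]
  p1 <- frame$positions[f[, 1], , drop = FALSE]
  p2 <- frame$positions[f[, 2], , drop = FALSE]
  p3 <- frame$positions[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  # outward area vectors (facets stored outward-ordered)
  av <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  vbar <- (frame$velocity[f[, 1], , drop = FALSE] +
           frame$velocity[f[, 2], , drop = FALSE] +
           frame$velocity[f[, 3], , drop = FALSE]) / 3
  q_out <- sum(rowSums(av * vbar))  # m^3/s, positive outward
  type <- mesh$patches$type[match(patch, mesh$patches$name)]
  sgn <- if (identical(type, "inlet")) -1 else 1
  sgn * q_out * 1e6
}

# area-weighted average of a nodal scalar over a patch, plus patch area (m^2)
patchAverage <- function(frame, patch, values) {
  mesh <- frame$mesh
  idx <- patchFacets(mesh, patch)
  f <- mesh$facets[idx, , drop = FALSE]
  p1 <- frame$positions[f[, 1], , drop = FALSE]
  e1 <- frame$positions[f[, 2], , drop = FALSE] - p1
  e2 <- frame$positions[f[, 3], , drop = FALSE] - p1
  av <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  area <- sqrt(rowSums(av^2))
  vbar <- (values[f[, 1]] + values[f[, 2]] + values[f[, 3]]) / 3
  list(average = sum(area * vbar) / sum(area), area = sum(area))
}

#' Planar cross-section of a branch
#'
#' Intersects the mesh (at the frame's node positions) with a plane and
#' returns the cut area. The cut must form a single connected component
#' within the named branch; a plane missing the branch or cutting several
#' disconnected components is an error.
#'
#' @param frame A [fieldFrame()].
#' @param plane `list(point = c(x,y,z), normal = c(x,y,z))` in m.
#' @param branch Optional branch label used to restrict candidate cells when
#'   the mesh carries `cell_region` tags.
#' @return `list(area_cm2, n_cells, centroid)`: cut area in cm^2, the number
#'   of cut cells, and the area centroid (m).
#' @export
crossSection <- function(frame, plane, branch = NULL) {
  mesh <- frame$mesh
  pos <- frame$positions
  nrm <- plane$normal / sqrt(sum(plane$normal^2))
  d <- as.vector((pos - matrix(plane$point, nrow(pos), 3, byrow = TRUE)) %*% nrm)
  # nudge on-plane nodes to the positive side so node-aligned planes cut once
  eps <- 1e-12 * max(abs(d), 1e-30)
  d[abs(d) < eps] <- eps

  dt <- matrix(d[mesh$tets], ncol = 4)
  cut <- which(matrixStats_rowMins(dt) < 0 & matrixStats_rowMaxs(dt) > 0)
  if (!is.null(branch) && !is.null(mesh$cell_region)) {
    cut_b <- cut[mesh$cell_region[cut] == branch]
    if (length(cut_b) == 0 && length(cut) == 0) {
      stop("plane misses branch ", branch)
    }
    if (length(cut_b) == 0) {
      stop("plane misses branch ", branch, " (cuts only other regions)")
    }
    cut <- cut_b
  }
  if (length(cut) == 0) stop("plane misses the mesh")

  # connected components of the cut cells via face adjacency
  comp <- .components(mesh$neighbors, cut)
  if (max(comp) > 1) {
    stop(sprintf("cross-section cut is not a single component (%d components of sizes %s)",
                 max(comp), paste(tabulate(comp), collapse = ", ")))
  }

  # per-cell intersection polygon areas
  basis <- .planeBasis(nrm)
  total <- 0
  cx <- c(0, 0, 0)
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (ci in cut) {
    vid <- mesh$tets[ci, ]
    dv <- d[vid]
    pts <- NULL
    for (e in seq_len(6)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      if (dv[i] * dv[j] < 0) {
        tpar <- dv[i] / (dv[i] - dv[j])
        pts <- rbind(pts, pos[vid[i], ] + tpar * (pos[vid[j], ] - pos[vid[i], ]))
      }
    }
    if (is.null(pts) || nrow(pts) < 3) next
    uvp <- pts %*% basis
    ctr <- colMeans(uvp)
    o <- order(atan2(uvp[, 2] - ctr[2], uvp[, 1] - ctr[1]))
    uvo <- uvp[o, , drop = FALSE]
    aa <- abs(sum(uvo[, 1] * uvo[c(2:nrow(uvo), 1), 2] -
                  uvo[c(2:nrow(uvo), 1), 1] * uvo[, 2])) / 2
    total <- total + aa
    cx <- cx + aa * colMeans(pts)
  }
  if (total <= 0) stop("plane misses the mesh (degenerate cut)")
  list(area_cm2 = total * 1e4, n_cells = length(cut), centroid = cx / total)
}

# two orthonormal in-plane basis vectors for a unit normal
.planeBasis <- function(nrm) {
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- ref - sum(ref * nrm) * nrm
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(nrm[2] * b1[3] - nrm[3] * b1[2],
          nrm[3] * b1[1] - nrm[1] * b1[3],
          nrm[1] * b1[2] - nrm[2] * b1[1])
  cbind(b1, b2)
}

# connected components of a cell subset under face adjacency; returns
# component id per element of `cells`
.components <- function(neighbors, cells) {
  idx <- integer(max(neighbors, cells, na.rm = TRUE))
  idx[cells] <- seq_along(cells)
  comp <- integer(length(cells))
  cid <- 0L
  for (start in seq_along(cells)) {
    if (comp[start] > 0) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nbs <- neighbors[cells[cur], ]
      nbs <- nbs[!is.na(nbs)]
      loc <- idx[nbs]
      loc <- loc[loc > 0]
      loc <- loc[comp[loc] == 0]
      if (length(loc) > 0) {
        comp[loc] <- cid
        queue <- c(queue, loc)
      }
    }
  }
  comp
}

# minimal row-min / row-max helpers (avoid a matrixStats dependency)
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))
matrixStats_rowMaxs <- function(m) do.call(pmax, as.data.frame(m))
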