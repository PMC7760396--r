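#' Tetrahedral TCPC mesh with labeled boundary patches
#'
#' Container for an unstructured tetrahedral mesh of a four-branch total
#' cavopulmonary connection. Boundary facets carry patch labels from
#' `FP`, `SVC`, `LPA`, `RPA`, `WALL`; the four cap patches are planar and
#' registered as inlets (`FP`, `SVC`) or outlets (`LPA`, `RPA`).
#'
#' Node coordinates are in meters. Tetrahedra are stored with positive
#' orientation (all signed volumes > 0); boundary facets are stored with
#' outward orientation so that `cross(B-A, C-A)/2` is the outward area vector.
#'
#' @param nodes Numeric n x 3 matrix of node coordinates (m).
#' @param tets Integer m x 4 matrix of node indices (1-based).
#' @param facets Integer f x 3 matrix of boundary triangle node indices,
#'   outward-ordered.
#' @param facet_patch Character vector of length f with values in
#'   `FP`, `SVC`, `LPA`, `RPA`, `WALL`.
#' @param patches Data frame registering the cap patches: columns `name`,
#'   `type` (`"inlet"`/`"outlet"`), plane center `cx, cy, cz` (m), outward
#'   normal `nx, ny, nz`, and `radius` (m).
#' @param cell_region Optional character vector (length m) tagging each cell
#'   with the branch it belongs to (`FP`, `SVC`, `LPA`, `RPA`, `JUNCTION`).
#' @param node_meta Optional per-node metadata data frame (used by the
#'   synthetic generator).
#' @param validate Run the full validity checks (watertightness, orientation,
#'   cap planarity). Disable only for meshes already validated.
#' @return An object of class `tcpc_mesh`.
#' @export
tcpcMesh <- function(nodes, tets, facets, facet_patch, patches,
                     cell_region = NULL, node_meta = NULL, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  facets <- as.matrix(facets)
  storage.mode(facets) <- "integer"
  facet_patch <- as.character(facet_patch)
  stopifnot(ncol(nodes) == 3, ncol(tets) == 4, ncol(facets) == 3)
  if (length(facet_patch) != nrow(facets)) {
    stop("facet_patch must have one label per boundary facet")
  }
  bad <- setdiff(unique(facet_patch), c("FP", "SVC", "LPA", "RPA", "WALL"))
  if (length(bad) > 0) stop("unknown patch labels: ", paste(bad, collapse = ", "))

  mesh <- structure(
    list(nodes = nodes, tets = tets, facets = facets,
         facet_patch = facet_patch, patches = patches,
         cell_region = cell_region, node_meta = node_meta,
         neighbors = NULL),
    class = "tcpc_mesh"
  )
  mesh$neighbors <- tetNeighbors(tets)
  if (validate) validateMesh(mesh)
  mesh
}

#' @export
print.tcpc_mesh <- function(x, ...) {
  cat(sprintf("TCPC mesh: %d nodes, %d tetrahedra, %d boundary facets\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$facets)))
  tb <- table(x$facet_patch)
  cat("  patches:", paste(sprintf("%s(%d)", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

# Signed volumes of all tetrahedra for a given node position matrix.
tetVolumes <- function(tets, pos) {
  a <- pos[tets[, 1], , drop = FALSE]
  b <- pos[tets[, 2], , drop = FALSE] - a
  c_ <- pos[tets[, 3], , drop = FALSE] - a
  d <- pos[tets[, 4], , drop = FALSE] - a
  # det [b c d] / 6 via scalar triple product
  cx <- c_[, 2] * d[, 3] - c_[, 3] * d[, 2]
  cy <- c_[, 3] * d[, 1] - c_[, 1] * d[, 3]
  cz <- c_[, 1] * d[, 2] - c_[, 2] * d[, 1]
  (b[, 1] * cx + b[, 2] * cy + b[, 3] * cz) / 6
}

#' Total mesh volume
#'
#' @param mesh A [tcpcMesh()].
#' @param positions Optional node positions (defaults to reference
#'   coordinates), e.g. a deformed frame's positions.
#' @return Volume in m^3.
#' @export
meshVolume <- function(mesh, positions = NULL) {
  if (is.null(positions)) positions <- mesh$nodes
  sum(tetVolumes(mesh$tets, positions))
}

# Local outward face orderings of a positively oriented tetrahedron:
# row r = face opposite local vertex r.
.tetFaceOrder <- rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))

# All 4m faces of the tets, outward-ordered, plus (tet, local face) ids.
allTetFaces <- function(tets) {
  m <- nrow(tets)
  fo <- .tetFaceOrder
  faces <- rbind(tets[, fo[1, ]], tets[, fo[2, ]], tets[, fo[3, ]], tets[, fo[4, ]])
  list(faces = faces,
       tet = rep(seq_len(m), times = 4),
       local = rep(1:4, each = m))
}

# Face-adjacency (neighbor) table: neighbors[t, f] = tet sharing the face of
# t opposite local vertex f, or NA at the boundary.
tetNeighbors <- function(tets) {
  af <- allTetFaces(tets)
  key <- .faceKey(af$faces)
  o <- order(key[, 1], key[, 2], key[, 3])
  k <- key[o, , drop = FALSE]
  same <- c(FALSE, rowSums(k[-1, , drop = FALSE] == k[-nrow(k), , drop = FALSE]) == 3)
  nb <- matrix(NA_integer_, nrow(tets), 4)
  prs <- which(same)
  i1 <- o[prs - 1L]
  i2 <- o[prs]
  nb[cbind(af$tet[i1], af$local[i1])] <- af$tet[i2]
  nb[cbind(af$tet[i2], af$local[i2])] <- af$tet[i1]
  nb
}

# sorted (min, mid, max) key columns for a 3-column face matrix
.faceKey <- function(faces) {
  lo <- pmin.int(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax.int(faces[, 1], faces[, 2], faces[, 3])
  cbind(lo, faces[, 1] + faces[, 2] + faces[, 3] - lo - hi, hi)
}

# Boundary faces (appearing once across all tet faces), outward ordering kept.
boundaryFaces <- function(tets) {
  af <- allTetFaces(tets)
  srt <- .faceKey(af$faces)
  o <- order(srt[, 1], srt[, 2], srt[, 3])
  k <- srt[o, , drop = FALSE]
  n <- nrow(k)
  dup_next <- c(rowSums(k[-n, , drop = FALSE] == k[-1, , drop = FALSE]) == 3, FALSE)
  dup_prev <- c(FALSE, dup_next[-n])
  solo <- o[!(dup_next | dup_prev)]
  list(faces = af$faces[solo, , drop = FALSE], tet = af$tet[solo])
}

#' Validate mesh invariants
#'
#' Checks positive cell volumes, watertightness (every tet face shared by two
#' cells or present exactly once as a labeled boundary facet), and planarity
#' of the four cap patches.
#'
#' @param mesh A [tcpcMesh()].
#' @param planar_tol Relative tolerance for cap planarity (fraction of cap
#'   radius).
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validateMesh <- function(mesh, planar_tol = 1e-6) {
  vol <- tetVolumes(mesh$tets, mesh$nodes)
  if (any(vol <= 0)) {
    stop(sprintf("%d cells with non-positive volume (first: cell %d)",
                 sum(vol <= 0), which(vol <= 0)[1]))
  }
  bf <- boundaryFaces(mesh$tets)
  keyOf <- function(f) {
    s <- .faceKey(f)
    paste(s[, 1], s[, 2], s[, 3])
  }
  kb <- keyOf(bf$faces)
  kf <- keyOf(mesh$facets)
  if (!setequal(kb, kf) || anyDuplicated(kf)) {
    stop("boundary facet set is not closed: labeled facets do not match ",
         "the topological boundary")
  }
  for (i in seq_len(nrow(mesh$patches))) {
    p <- mesh$patches[i, ]
    idx <- unique(as.vector(mesh$facets[mesh$facet_patch == p$name, ]))
    if (length(idx) == 0) stop("cap patch has no facets: ", p$name)
    d <- (mesh$nodes[idx, , drop = FALSE] -
            matrix(c(p$cx, p$cy, p$cz), length(idx), 3, byrow = TRUE)) %*%
      c(p$nx, p$ny, p$nz)
    if (max(abs(d)) > planar_tol * max(p$radius, 1e-9)) {
      stop(sprintf("cap patch %s not planar (max deviation %.3g m)",
                   p$name, max(abs(d))))
    }
  }
  invisible(TRUE)
}

# facet row indices for a patch, with existence check
patchFacets <- function(mesh, patch) {
  idx <- which(mesh$facet_patch == patch)
  if (length(idx) == 0) stop("unknown patch label: ", patch)
  idx
}

# names of non-wall patches present
capNames <- function(mesh) as.character(mesh$patches$name)
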