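# Structured tetrahedral mesh construction for the idealized TCPC junction
# and the straight-pipe fixture.
#
# Both geometries are built from hexahedral blocks (a central cube with four
# tube arms, or a single extruded tube) whose cross-sections are images of the
# logical square [-1,1]^2. Each cross-section morphs smoothly from the square
# junction face to an exact circle over a transition length, so every cap is
# an exact (polygonal) disc. Hexes are split into 6 tetrahedra by the Kuhn
# (Freudenthal) decomposition, which is conforming across identical blocks.

.smoothstep <- function(t) {
  t <- pmin(1, pmax(0, t))
  t * t * (3 - 2 * t)
}

# Square-to-disc map blended with the identity square map.
# u, v in [-1,1]; returns in-plane coordinates for blend weight w in [0,1]:
# w = 0 gives the square of half-side a, w = 1 the disc of radius R.
.blendSection <- function(u, v, w, a, R) {
  xs <- a * u
  ys <- a * v
  xc <- R * u * sqrt(1 - v^2 / 2)
  yc <- R * v * sqrt(1 - u^2 / 2)
  list(X = (1 - w) * xs + w * xc, Y = (1 - w) * ys + w * yc)
}

# Normalized squared radial coordinate of the blend family: 1 on the wall,
# 0 on the axis, for every blend weight.
.rhoSq <- function(u, v) pmin(1, u^2 + v^2 - u^2 * v^2)

# Cross-section area of the blended section is quadratic in w (the map is
# affine in w). Coefficients fixed by A(0) = 4 a^2, A(1) = pi R^2 and a
# numerically integrated midpoint value.
.sectionAreaFun <- function(a, R, nq = 400) {
  h <- 2 / nq
  gq <- seq(-1 + h / 2, 1 - h / 2, length.out = nq)
  u <- matrix(gq, nq, nq)
  v <- matrix(gq, nq, nq, byrow = TRUE)
  # |J| at w = 1/2 via analytic partials of the blended map
  jac <- function(w) {
    xu <- (1 - w) * a + w * R * sqrt(1 - v^2 / 2)
    xv <- w * R * u * (-v / 2) / sqrt(1 - v^2 / 2)
    yu <- w * R * v * (-u / 2) / sqrt(1 - u^2 / 2)
    yv <- (1 - w) * a + w * R * sqrt(1 - u^2 / 2)
    sum(xu * yv - xv * yu) * h * h
  }
  Ah <- jac(0.5)
  A0 <- 4 * a^2
  A1 <- pi * R^2
  # A(w) = A0 + b w + c w^2 with A(1) and A(0.5) constraints
  cc <- 2 * A1 + 2 * A0 - 4 * Ah
  bb <- A1 - A0 - cc
  function(w) A0 + bb * w + cc * w^2
}

.kuhnPattern <- matrix(c(1, 2, 4, 8,
                         1, 2, 6, 8,
                         1, 3, 4, 8,
                         1, 3, 7, 8,
                         1, 5, 6, 8,
                         1, 5, 7, 8), ncol = 4, byrow = TRUE)

.hexesToTets <- function(H) {
  do.call(rbind, lapply(seq_len(6), function(r) H[, .kuhnPattern[r, ], drop = FALSE]))
}

# Fix tet orientation in place so all signed volumes are positive.
.orientTets <- function(tets, pos) {
  vol <- tetVolumes(tets, pos)
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tets[flip, 3]
    tets[flip, 3] <- tets[flip, 4]
    tets[flip, 4] <- tmp
  }
  tets
}

# Hex connectivity of a structured (ni x nj x nk cells) block given a node id
# lookup array id[i+1, j+1, k+1] (i = 0..ni).
.blockHexes <- function(id, ni, nj, nk) {
  i <- rep(seq_len(ni), times = nj * nk)
  j <- rep(rep(seq_len(nj), each = ni), times = nk)
  k <- rep(seq_len(nk), each = ni * nj)
  idx <- function(di, dj, dk) id[cbind(i + di, j + dj, k + dk)]
  cbind(idx(0, 0, 0), idx(1, 0, 0), idx(0, 1, 0), idx(1, 1, 0),
        idx(0, 0, 1), idx(1, 0, 1), idx(0, 1, 1), idx(1, 1, 1))
}

.branchFrames <- list(
  FP  = list(axis = c(0, 0, -1), e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
  SVC = list(axis = c(0, 0, 1),  e1 = c(1, 0, 0), e2 = c(0, 1, 0)),
  LPA = list(axis = c(-1, 0, 0), e1 = c(0, 1, 0), e2 = c(0, 0, 1)),
  RPA = list(axis = c(1, 0, 0),  e1 = c(0, 1, 0), e2 = c(0, 0, 1))
)

#' Build the idealized four-branch TCPC mesh
#'
#' Constructs a watertight labeled tetrahedral mesh of an idealized total
#' cavopulmonary connection: a central junction box with four tube arms
#' (FP inlet from below, SVC inlet from above, LPA/RPA outlets laterally).
#' Each arm's cross-section morphs smoothly from the junction face to an
#' exact circle of the configured radius, so all four caps are planar discs.
#' The Fontan-pathway arm can be sheared laterally by the configured junction
#' offset. The build is fully deterministic for a fixed configuration.
#'
#' @param config A [syntheticConfig()].
#' @return A [tcpcMesh()] with `cell_region` and `node_meta` filled in.
#' @examples
#' mesh <- buildIdealizedTcpc(syntheticConfig(edge_length = 4.5))
#' mesh
#' @export
buildIdealizedTcpc <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  radii <- config$radii_m
  lengths <- config$lengths_m
  a <- config$junction_half_width_m
  edge <- config$edge_length_m
  offset <- config$junction_offset_m
  if (offset >= 0.6 * lengths[["FP"]]) {
    stop("junction offset too large for the FP arm length: non-manifold junction")
  }

  n <- max(4L, 2L * ceiling(a / edge))  # even divisions across the junction box
  g <- seq(-1, 1, length.out = n + 1)
  np1 <- n + 1L

  cube_pos <- as.matrix(expand.grid(x = a * g, y = a * g, z = a * g))
  dimnames(cube_pos) <- NULL
  n_cube <- np1^3
  cube_id <- array(seq_len(n_cube), dim = c(np1, np1, np1))

  branch_names <- c("FP", "SVC", "LPA", "RPA")
  uv <- expand.grid(u = g, v = g)  # u fastest; local id = 1 + i + np1*j

  pos_list <- list(cube_pos)
  meta_region <- rep("JUNCTION", n_cube)
  meta_s <- rep(NA_real_, n_cube)
  meta_u <- rep(NA_real_, n_cube)
  meta_v <- rep(NA_real_, n_cube)
  meta_station <- rep(NA_integer_, n_cube)

  offset_node <- n_cube
  branch_info <- list()
  hexes <- list()
  hex_region <- list()

  # cube block hexes
  hexes[["JUNCTION"]] <- .blockHexes(cube_id, n, n, n)
  hex_region[["JUNCTION"]] <- rep("JUNCTION", n^3)

  # cube face node id lookup (np1 x np1) per branch, indexed like (u, v)
  face_ids <- list(
    FP  = cube_id[, , 1],
    SVC = cube_id[, , np1],
    LPA = cube_id[1, , ],
    RPA = cube_id[np1, , ]
  )

  for (b in branch_names) {
    fr <- .branchFrames[[b]]
    R <- radii[[b]]
    L <- lengths[[b]]
    n_ax <- max(3L, ceiling(L / edge))
    s_tr <- config$transition_fraction * L
    s_k <- seq_len(n_ax) * L / n_ax
    n_sec <- np1^2

    # station node positions
    ppos <- matrix(0, n_ax * n_sec, 3)
    ps <- numeric(n_ax * n_sec)
    for (k in seq_len(n_ax)) {
      s <- s_k[k]
      w <- .smoothstep(s / s_tr)
      sec <- .blendSection(uv$u, uv$v, w, a, R)
      base <- matrix(fr$axis * (a + s), n_sec, 3, byrow = TRUE)
      if (b == "FP" && offset != 0) {
        base[, 1] <- base[, 1] + offset * .smoothstep(s / L)
      }
      rows <- (k - 1) * n_sec + seq_len(n_sec)
      ppos[rows, ] <- base +
        outer(sec$X, fr$e1) + outer(sec$Y, fr$e2)
      ps[rows] <- s
    }
    pos_list[[length(pos_list) + 1]] <- ppos
    meta_region <- c(meta_region, rep(b, n_ax * n_sec))
    meta_s <- c(meta_s, ps)
    meta_u <- c(meta_u, rep(uv$u, n_ax))
    meta_v <- c(meta_v, rep(uv$v, n_ax))
    meta_station <- c(meta_station, rep(seq_len(n_ax), each = n_sec))

    # node id lookup over stations 0..n_ax: station 0 = cube face
    id <- array(0L, dim = c(np1, np1, n_ax + 1L))
    id[, , 1] <- face_ids[[b]]
    blk <- array(offset_node + seq_len(n_ax * n_sec), dim = c(np1, np1, n_ax))
    id[, , 2:(n_ax + 1L)] <- blk

    hexes[[b]] <- .blockHexes(id, n, n, n_ax)
    hex_region[[b]] <- rep(b, n^2 * n_ax)

    areaFun <- .sectionAreaFun(a, R)
    w_k <- .smoothstep(s_k / s_tr)
    branch_info[[b]] <- list(
      n_ax = n_ax, s = s_k, w = w_k, area = areaFun(w_k),
      cap_nodes = as.vector(id[, , n_ax + 1L]),
      s_tr = s_tr, radius = R, length = L,
      axis = fr$axis, e1 = fr$e1, e2 = fr$e2
    )
    offset_node <- offset_node + n_ax * n_sec
  }

  nodes <- do.call(rbind, pos_list)
  H <- do.call(rbind, hexes)
  region_hex <- unlist(hex_region, use.names = FALSE)
  tets <- .hexesToTets(H)
  cell_region <- rep(region_hex, times = 6)
  tets <- .orientTets(tets, nodes)

  bf <- boundaryFaces(tets)
  facet_patch <- rep("WALL", nrow(bf$faces))
  for (b in branch_names) {
    capset <- branch_info[[b]]$cap_nodes
    on_cap <- matrix(bf$faces %in% capset, ncol = 3)
    facet_patch[rowSums(on_cap) == 3] <- b
  }

  cap_center <- function(b) {
    fr <- .branchFrames[[b]]
    ctr <- fr$axis * (a + lengths[[b]])
    if (b == "FP") ctr <- ctr + c(offset, 0, 0)
    ctr
  }
  patches <- do.call(rbind, lapply(branch_names, function(b) {
    ctr <- cap_center(b)
    ax <- .branchFrames[[b]]$axis
    data.frame(name = b,
               type = if (b %in% c("FP", "SVC")) "inlet" else "outlet",
               cx = ctr[1], cy = ctr[2], cz = ctr[3],
               nx = ax[1], ny = ax[2], nz = ax[3],
               radius = radii[[b]], stringsAsFactors = FALSE)
  }))

  node_meta <- data.frame(region = meta_region, s = meta_s,
                          u = meta_u, v = meta_v, station = meta_station,
                          stringsAsFactors = FALSE)

  mesh <- tcpcMesh(nodes, tets, bf$faces, facet_patch, patches,
                   cell_region = cell_region, node_meta = node_meta,
                   validate = TRUE)
  mesh$branch_info <- branch_info
  mesh$junction_half_width <- a
  mesh$config <- config
  mesh
}

#' Build a straight circular pipe mesh
#'
#' Extruded-disc tetrahedral mesh of a straight tube along +z with an inlet
#' cap (labeled `FP`) at z = 0 and an outlet cap (labeled `LPA`) at z = L.
#' Used by [poiseuilleFixture()] and as the analytic-oracle geometry for
#' cross-section areas, boundary fluxes and particle transit times.
#'
#' @param radius_cm Tube radius in cm.
#' @param length_cm Tube length in cm.
#' @param edge_mm Target mesh edge length in mm.
#' @return A [tcpcMesh()].
#' @export
buildPipeMesh <- function(radius_cm, length_cm, edge_mm = 2) {
  R <- radius_cm / 100
  L <- length_cm / 100
  edge <- edge_mm / 1000
  n <- max(4L, 2L * ceiling(R / edge))
  n_ax <- max(3L, ceiling(L / edge))
  g <- seq(-1, 1, length.out = n + 1)
  np1 <- n + 1L
  uv <- expand.grid(u = g, v = g)
  n_sec <- np1^2
  sec <- .blendSection(uv$u, uv$v, 1, R, R)

  s_k <- seq(0, L, length.out = n_ax + 1)
  nodes <- do.call(rbind, lapply(seq_along(s_k), function(k) {
    cbind(sec$X, sec$Y, s_k[k])
  }))
  id <- array(seq_len(n_sec * (n_ax + 1L)), dim = c(np1, np1, n_ax + 1L))

  H <- .blockHexes(id, n, n, n_ax)
  tets <- .hexesToTets(H)
  tets <- .orientTets(tets, nodes)

  bf <- boundaryFaces(tets)
  inlet_nodes <- as.vector(id[, , 1])
  outlet_nodes <- as.vector(id[, , n_ax + 1L])
  facet_patch <- rep("WALL", nrow(bf$faces))
  facet_patch[rowSums(matrix(bf$faces %in% inlet_nodes, ncol = 3)) == 3] <- "FP"
  facet_patch[rowSums(matrix(bf$faces %in% outlet_nodes, ncol = 3)) == 3] <- "LPA"

  patches <- data.frame(
    name = c("FP", "LPA"), type = c("inlet", "outlet"),
    cx = 0, cy = 0, cz = c(0, L),
    nx = 0, ny = 0, nz = c(-1, 1),
    radius = R, stringsAsFactors = FALSE
  )
  node_meta <- data.frame(
    region = "PIPE",
    s = rep(s_k, each = n_sec),
    u = rep(uv$u, n_ax + 1L), v = rep(uv$v, n_ax + 1L),
    station = rep(seq_len(n_ax + 1L) - 1L, each = n_sec),
    stringsAsFactors = FALSE
  )
  mesh <- tcpcMesh(nodes, tets, bf$faces, facet_patch, patches,
                   cell_region = rep("PIPE", nrow(tets)),
                   node_meta = node_meta, validate = TRUE)
  mesh$pipe <- list(radius = R, length = L)
  mesh
}
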