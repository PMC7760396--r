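# Field-series I/O: per-frame VTK legacy / VTU files plus a YAML manifest.
#
# The manifest lists the mesh connectivity file, a facet/patch sidecar table
# (legacy VTK carries no facet labels), the cap-patch registry, units, the
# period and the per-frame files with their times. Numbers are written with
# full precision so a write/read round trip is the identity.

.num <- function(x) sprintf("%.17g", x)

.writeVtkLegacy <- function(file, points, cells, point_data) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tcpcflow field frame", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(points))), con)
  writeLines(paste(.num(points[, 1]), .num(points[, 2]), .num(points[, 3])), con)
  m <- nrow(cells)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(paste(4, cells[, 1] - 1, cells[, 2] - 1, cells[, 3] - 1,
                   cells[, 4] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", nrow(points)), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(paste(.num(v[, 1]), .num(v[, 2]), .num(v[, 3])), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(.num(v), con)
      }
    }
  }
  invisible(file)
}

.readVtkLegacy <- function(file) {
  txt <- readLines(file, warn = FALSE)
  tok_line <- function(pat) grep(pat, txt)[1]
  readBlock <- function(start, count, ncol) {
    vals <- scan(text = paste(txt[start + seq_len(ceiling(count))], collapse = "\n"),
                 quiet = TRUE)
    matrix(vals, ncol = ncol, byrow = TRUE)
  }
  ip <- tok_line("^POINTS ")
  if (is.na(ip)) stop("not a VTK unstructured grid: ", file)
  npts <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  points <- readBlock(ip, npts, 3)
  ic <- tok_line("^CELLS ")
  mc <- as.integer(strsplit(txt[ic], "\\s+")[[1]][2])
  cellrows <- readBlock(ic, mc, 5)
  if (any(cellrows[, 1] != 4)) stop("non-tetrahedral cells in ", file)
  cells <- cellrows[, 2:5, drop = FALSE] + 1L
  point_data <- list()
  ipd <- tok_line("^POINT_DATA ")
  if (!is.na(ipd)) {
    i <- ipd + 1
    while (i <= length(txt)) {
      ln <- txt[i]
      if (grepl("^VECTORS ", ln)) {
        nm <- strsplit(ln, "\\s+")[[1]][2]
        point_data[[nm]] <- readBlock(i, npts, 3)
        i <- i + npts + 1
      } else if (grepl("^SCALARS ", ln)) {
        nm <- strsplit(ln, "\\s+")[[1]][2]
        point_data[[nm]] <- as.vector(readBlock(i + 1, npts, 1))
        i <- i + npts + 2
      } else {
        i <- i + 1
      }
    }
  }
  list(points = points, cells = cells, point_data = point_data)
}

.writeVtu <- function(file, points, cells, point_data) {
  n <- nrow(points)
  m <- nrow(cells)
  # values: n_entities x ncomp matrix; one line per entity
  da <- function(name, values, ncomp) {
    values <- matrix(values, ncol = ncomp)
    lines <- do.call(paste, lapply(seq_len(ncomp), function(j) .num(values[, j])))
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, ncomp, paste(lines, collapse = "\n"))
  }
  pd <- if (length(point_data) > 0) {
    paste0("<PointData>\n",
           paste(vapply(names(point_data), function(nm) {
             v <- point_data[[nm]]
             if (is.matrix(v)) da(nm, v, 3) else da(nm, v, 1)
           }, character(1)), collapse = "\n"),
           "\n</PointData>\n")
  } else ""
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    "<UnstructuredGrid>\n",
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">\n', n, m),
    "<Points>\n", da("Points", points, 3), "\n</Points>\n",
    "<Cells>\n",
    sprintf('<DataArray type="Int64" Name="connectivity" format="ascii">\n%s\n</DataArray>\n',
            paste(as.vector(t(cells - 1L)), collapse = " ")),
    sprintf('<DataArray type="Int64" Name="offsets" format="ascii">\n%s\n</DataArray>\n',
            paste(seq_len(m) * 4L, collapse = " ")),
    sprintf('<DataArray type="UInt8" Name="types" format="ascii">\n%s\n</DataArray>\n',
            paste(rep(10L, m), collapse = " ")),
    "</Cells>\n", pd,
    "</Piece>\n</UnstructuredGrid>\n</VTKFile>\n"
  )
  writeLines(xml, file)
  invisible(file)
}

.readVtu <- function(file) {
  doc <- xml2::read_xml(file)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  getArr <- function(xpath) {
    nd <- xml2::xml_find_first(piece, xpath)
    if (inherits(nd, "xml_missing")) return(NULL)
    scan(text = xml2::xml_text(nd), quiet = TRUE)
  }
  pts <- getArr(".//Points/DataArray")
  points <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- getArr(".//Cells/DataArray[@Name='connectivity']")
  cells <- matrix(as.integer(conn), ncol = 4, byrow = TRUE) + 1L
  point_data <- list()
  for (nd in xml2::xml_find_all(piece, ".//PointData/DataArray")) {
    nm <- xml2::xml_attr(nd, "Name")
    ncomp <- as.integer(xml2::xml_attr(nd, "NumberOfComponents"))
    vals <- scan(text = xml2::xml_text(nd), quiet = TRUE)
    point_data[[nm]] <- if (!is.na(ncomp) && ncomp == 3) {
      matrix(vals, ncol = 3, byrow = TRUE)
    } else as.vector(vals)
  }
  list(points = points, cells = cells, point_data = point_data)
}

#' Write a field series to disk
#'
#' Writes one file per frame (VTK legacy or VTU, ASCII), a mesh connectivity
#' file, sidecar tables with the labeled boundary facets and the cap-patch
#' registry, and a YAML manifest tying everything together.
#' [readFieldSeries()] of the result reproduces the series exactly.
#'
#' @param series A [fieldSeries()].
#' @param dir Output directory (created if needed).
#' @param format `"vtk"` (legacy ASCII) or `"vtu"` (XML ASCII).
#' @return The manifest path, invisibly.
#' @export
writeFieldSeries <- function(series, dir, format = c("vtk", "vtu")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "field_series"))
  if (length(series$frames) == 0) stop("empty frame list")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- series$mesh
  wr <- if (format == "vtk") .writeVtkLegacy else .writeVtu
  meshfile <- paste0("mesh.", format)
  wr(file.path(dir, meshfile), mesh$nodes, mesh$tets, list())
  utils::write.csv(
    data.frame(n1 = mesh$facets[, 1], n2 = mesh$facets[, 2],
               n3 = mesh$facets[, 3], patch = mesh$facet_patch),
    file.path(dir, "facets.csv"), row.names = FALSE)
  utils::write.csv(mesh$patches, file.path(dir, "patches.csv"),
                   row.names = FALSE)
  frame_files <- sprintf("frame_%04d.%s", seq_along(series$frames) - 1, format)
  for (i in seq_along(series$frames)) {
    f <- series$frames[[i]]
    wr(file.path(dir, frame_files[i]), f$positions, mesh$tets,
       list(velocity = f$velocity, pressure = f$pressure))
  }
  manifest <- list(
    format = "tcpcflow-field-series/1",
    period = series$period,
    periodic = series$periodic,
    units = list(length = "m", velocity = "m/s", pressure = "Pa", time = "s"),
    mesh = list(file = meshfile, facets = "facets.csv", patches = "patches.csv"),
    patch_types = as.list(stats::setNames(mesh$patches$type, mesh$patches$name)),
    frames = lapply(seq_along(series$frames), function(i) {
      list(file = frame_files[i], time = series$times[i])
    })
  )
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path, precision = 17)
  invisible(manifest_path)
}

#' Read a field series from a manifest
#'
#' Loads the mesh, labeled boundary facets, cap-patch registry and all frames
#' referenced by a manifest written by [writeFieldSeries()] (or assembled by
#' hand from per-frame VTK legacy / VTU files plus the sidecar tables).
#'
#' @param manifest_path Path to the YAML manifest.
#' @return A validated [fieldSeries()].
#' @export
readFieldSeries <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) stop("missing frame file: ", file)
    if (grepl("\\.vtu$", file)) .readVtu(path) else .readVtkLegacy(path)
  }
  mm <- rd(man$mesh$file)
  fac <- utils::read.csv(file.path(dir, man$mesh$facets),
                         stringsAsFactors = FALSE)
  if (!all(c("n1", "n2", "n3", "patch") %in% names(fac))) {
    stop("facet sidecar table lacks n1,n2,n3,patch columns")
  }
  if (any(!fac$patch %in% c("FP", "SVC", "LPA", "RPA", "WALL"))) {
    stop("unlabeled or unknown patches in facet table")
  }
  patches <- utils::read.csv(file.path(dir, man$mesh$patches),
                             stringsAsFactors = FALSE)
  mesh <- tcpcMesh(mm$points, mm$cells, as.matrix(fac[, c("n1", "n2", "n3")]),
                   fac$patch, patches, validate = TRUE)
  times <- vapply(man$frames, function(f) as.numeric(f$time), numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0)) stop("non-monotone times")
  frames <- lapply(man$frames, function(fm) {
    dat <- rd(fm$file)
    if (nrow(dat$points) != nrow(mesh$nodes)) {
      stop(sprintf("frame %s has wrong node count (%d, mesh has %d)",
                   fm$file, nrow(dat$points), nrow(mesh$nodes)))
    }
    if (!identical(dim(dat$cells), dim(mesh$tets)) ||
        any(dat$cells != mesh$tets)) {
      stop("inconsistent connectivity in frame ", fm$file)
    }
    if (is.null(dat$point_data$velocity) || is.null(dat$point_data$pressure)) {
      stop("frame ", fm$file, " lacks velocity/pressure point data")
    }
    fieldFrame(mesh, as.numeric(fm$time), dat$point_data$velocity,
               dat$point_data$pressure, positions = dat$points)
  })
  fieldSeries(mesh, frames, as.numeric(man$period),
              periodic = isTRUE(man$periodic))
}
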