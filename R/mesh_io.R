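#' Export a surface mesh to STL or VTP
#'
#' STL is written as the usual binary little-endian format (80-byte header,
#' triangle count, 12 float32 + attribute per facet). VTP is written as ASCII
#' XML PolyData; optional per-vertex scalar arrays are stored as PointData.
#'
#' @param mesh A `coro_mesh`.
#' @param path Output file path.
#' @param format `"stl"` or `"vtp"`; defaults to the file extension.
#' @param point_data Optional named list of per-vertex numeric vectors
#'   (VTP only).
#' @return `path`, invisibly.
#' @examples
#' mesh <- build_surface_mesh(stenosed_radius_profile(stenosis_spec("LM", 0.5)))
#' f <- tempfile(fileext = ".stl")
#' export_mesh(mesh, f)
#' @export
export_mesh <- function(mesh, path, format = NULL, point_data = NULL) {
  stopifnot(inherits(mesh, "coro_mesh"))
  if (nrow(mesh$triangles) == 0L) {
    stop("cannot export an empty mesh", call. = FALSE)
  }
  format <- tolower(format %||% tools::file_ext(path))
  switch(format,
    stl = write_stl_binary(mesh, path),
    vtp = write_vtp(mesh$vertices, mesh$triangles, path, point_data),
    stop("unknown mesh format: ", format, call. = FALSE)
  )
  invisible(path)
}

#' Import a surface mesh from STL or VTP
#'
#' Inverse of [export_mesh()]. STL facets are de-duplicated back into a shared
#' vertex table by exact coordinate match (binary STL stores float32, so a
#' round trip preserves vertex count exactly and total area to float32
#' precision). VTP PointData arrays are returned in `$point_data`.
#'
#' @param path File path.
#' @param format `"stl"` or `"vtp"`; defaults to the file extension.
#' @return A `coro_mesh` (without a generating profile); VTP meshes carry a
#'   `point_data` named list.
#' @export
import_mesh <- function(path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  out <- switch(format,
    stl = read_stl_binary(path),
    vtp = read_vtp(path),
    stop("unknown mesh format: ", format, call. = FALSE)
  )
  out
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("coroflow surface mesh", width = -80))
  writeBin(header[1:80], con)
  tri <- mesh$triangles
  writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
  v <- mesh$vertices
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  # 12 float32 per facet: normal, v1, v2, v3
  block <- t(cbind(nrm, a, b, c_))
  raw_f <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  dim(raw_f) <- c(48L, nrow(tri))
  attr_bytes <- matrix(as.raw(0), 2L, nrow(tri))
  writeBin(as.vector(rbind(raw_f, attr_bytes)), con)
  invisible(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  body <- readBin(con, "raw", ntri * 50L)
  dim(body) <- c(50L, ntri)
  floats <- readBin(as.vector(body[1:48, ]), "numeric", 12L * ntri,
                    size = 4, endian = "little")
  block <- matrix(floats, nrow = 12L)
  pts <- rbind(t(block[4:6, ]), t(block[7:9, ]), t(block[10:12, ]))
  ord <- c(t(matrix(seq_len(3L * ntri), ntri, 3L)))  # interleave v1,v2,v3 per facet
  pts <- pts[ord, , drop = FALSE]
  key <- paste(pts[, 1], pts[, 2], pts[, 3], sep = "|")
  idx <- match(key, unique(key))
  vertices <- pts[!duplicated(key), , drop = FALSE]
  triangles <- matrix(idx, ncol = 3, byrow = TRUE)
  structure(
    list(
      vertices = vertices,
      triangles = triangles,
      patch_area = triangle_areas(vertices, triangles),
      ring = NULL,
      z = vertices[, 3],
      profile = NULL
    ),
    class = "coro_mesh"
  )
}

num_fmt <- function(x) formatC(x, format = "g", digits = 17)

write_vtp <- function(vertices, triangles, path, point_data = NULL,
                      field_data = NULL, units = NULL) {
  n <- nrow(vertices)
  m <- nrow(triangles)
  unit_attr <- if (is.null(units)) "" else sprintf(' units="%s"', units)
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf('<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian"%s>',
            unit_attr),
    '  <PolyData>'
  )
  if (!is.null(field_data)) {
    lines <- c(lines, '    <FieldData>')
    for (nm in names(field_data)) {
      vals <- field_data[[nm]]
      lines <- c(
        lines,
        sprintf('      <DataArray type="Float64" Name="%s" NumberOfTuples="%d" format="ascii">',
                nm, length(vals)),
        paste(num_fmt(vals), collapse = " "),
        '      </DataArray>'
      )
    }
    lines <- c(lines, '    </FieldData>')
  }
  lines <- c(
    lines,
    sprintf('    <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">', n, m),
    '      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    paste(num_fmt(t(vertices)), collapse = " "),
    '        </DataArray>',
    '      </Points>'
  )
  if (!is.null(point_data) && length(point_data)) {
    stopifnot(!is.null(names(point_data)))
    lines <- c(lines, '      <PointData>')
    for (nm in names(point_data)) {
      vals <- point_data[[nm]]
      if (length(vals) != n) {
        stop("point_data array `", nm, "` has length ", length(vals),
             ", expected ", n, call. = FALSE)
      }
      lines <- c(
        lines,
        sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm),
        paste(num_fmt(vals), collapse = " "),
        '        </DataArray>'
      )
    }
    lines <- c(lines, '      </PointData>')
  }
  lines <- c(
    lines,
    '      <Polys>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">',
    paste(as.integer(t(triangles)) - 1L, collapse = " "),
    '        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">',
    paste(seq_len(m) * 3L, collapse = " "),
    '        </DataArray>',
    '      </Polys>',
    '    </Piece>',
    '  </PolyData>',
    '</VTKFile>'
  )
  writeLines(lines, path)
  invisible(path)
}

parse_ascii_numbers <- function(node) {
  as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
}

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  pts_node <- xml2::xml_find_first(piece, "./Points/DataArray")
  pts <- parse_ascii_numbers(pts_node)
  vertices <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- parse_ascii_numbers(
    xml2::xml_find_first(piece, './Polys/DataArray[@Name="connectivity"]')
  )
  triangles <- matrix(as.integer(conn) + 1L, ncol = 3, byrow = TRUE)
  pd_arrays <- xml2::xml_find_all(piece, "./PointData/DataArray")
  point_data <- NULL
  if (length(pd_arrays)) {
    point_data <- lapply(pd_arrays, parse_ascii_numbers)
    names(point_data) <- xml2::xml_attr(pd_arrays, "Name")
  }
  fd_arrays <- xml2::xml_find_all(doc, ".//FieldData/DataArray")
  field_data <- NULL
  if (length(fd_arrays)) {
    field_data <- lapply(fd_arrays, parse_ascii_numbers)
    names(field_data) <- xml2::xml_attr(fd_arrays, "Name")
  }
  mesh <- structure(
    list(
      vertices = vertices,
      triangles = triangles,
      patch_area = triangle_areas(vertices, triangles),
      ring = NULL,
      z = vertices[, 3],
      profile = NULL,
      point_data = point_data,
      field_data = field_data,
      units = xml2::xml_attr(doc, "units")
    ),
    class = "coro_mesh"
  )
  mesh
}
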