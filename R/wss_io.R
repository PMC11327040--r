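# WSS field I/O. Two interchange formats:
#  * VTP: mesh geometry + PointData arrays "wss_signed_<i>" with a FieldData
#    "time" array (or precomputed "tawss"/"osi" arrays), units declared as an
#    attribute on the VTKFile element;
#  * CSV: long table (vertex, time, wss) or per-vertex metrics
#    (vertex, tawss[, osi]) with a "# units: ..." comment line, plus a mesh
#    supplied by the caller.

WSS_UNITS <- "dyne/cm2"

#' Export a WSS field to VTP or CSV
#'
#' @param field A `coro_wss_field`.
#' @param path Output path.
#' @param format `"vtp"` or `"csv"`; defaults to the file extension.
#' @return `path`, invisibly.
#' @export
export_wss_field <- function(field, path, format = NULL) {
  stopifnot(inherits(field, "coro_wss_field"))
  format <- tolower(format %||% tools::file_ext(path))
  if (format == "vtp") {
    arrays <- lapply(seq_along(field$time), function(i) field$wss[, i])
    names(arrays) <- sprintf("wss_signed_%04d", seq_along(field$time) - 1L)
    write_vtp(field$mesh$vertices, field$mesh$triangles, path,
              point_data = arrays,
              field_data = list(time = field$time),
              units = WSS_UNITS)
  } else if (format == "csv") {
    long <- tibble::tibble(
      vertex = rep(seq_len(nrow(field$wss)), times = ncol(field$wss)),
      time = rep(field$time, each = nrow(field$wss)),
      wss = as.vector(field$wss)
    )
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# units: %s", WSS_UNITS), con)
    writeLines(readr::format_csv(long), con, sep = "")
  } else {
    stop("unknown WSS field format: ", format, call. = FALSE)
  }
  invisible(path)
}

#' Import a WSS field or precomputed WSS metrics
#'
#' Reads either a full signed-WSS time series (returned as a
#' `coro_wss_field`) or a file holding precomputed per-vertex TAWSS (and
#' optionally OSI) arrays (returned as a `coro_wss_metrics` container, usable
#' by [abnormal_areas()]; the OSI area is flagged unavailable when only TAWSS
#' is present). Units must be declared in the file (VTP attribute or CSV
#' comment) or supplied via `units`; only `"dyne/cm2"` is accepted.
#'
#' @param path Input path.
#' @param format `"vtp"` or `"csv"`; defaults to the file extension.
#' @param mesh A `coro_mesh`, required for CSV input (VTP carries its own
#'   geometry).
#' @param units Unit declaration overriding/absent from the file.
#' @return A `coro_wss_field` or `coro_wss_metrics` object.
#' @export
import_wss_field <- function(path, format = NULL, mesh = NULL, units = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  if (format == "vtp") {
    m <- import_mesh(path, "vtp")
    declared <- units %||% m$units
    check_wss_units(declared)
    pd <- m$point_data
    if (is.null(pd)) stop("VTP file has no PointData arrays", call. = FALSE)
    wss_names <- grep("^wss_signed_", names(pd), value = TRUE)
    if (length(wss_names)) {
      if (is.null(m$field_data$time)) {
        stop("VTP field is missing the `time` FieldData array", call. = FALSE)
      }
      tt <- m$field_data$time
      if (length(tt) != length(wss_names)) {
        stop("time array length does not match the number of WSS arrays",
             call. = FALSE)
      }
      wss <- do.call(cbind, pd[sort(wss_names)])
      return(new_wss_field(m, tt, wss))
    }
    if ("tawss" %in% names(pd)) {
      return(new_wss_metrics(m, pd$tawss, pd$osi))
    }
    stop("VTP file holds neither wss_signed_* nor tawss arrays", call. = FALSE)
  }
  if (format != "csv") stop("unknown WSS field format: ", format, call. = FALSE)

  if (is.null(mesh)) {
    stop("CSV import needs the surface `mesh` the field lives on",
         call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  declared <- units
  if (grepl("^#\\s*units:", first)) {
    declared <- declared %||% trimws(sub("^#\\s*units:", "", first))
  }
  check_wss_units(declared)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  nv <- nrow(mesh$vertices)
  if (all(c("vertex", "time", "wss") %in% names(df))) {
    tt <- sort(unique(df$time))
    if (nrow(df) != nv * length(tt) ||
        !setequal(unique(df$vertex), seq_len(nv))) {
      stop("CSV field is incomplete: expected every vertex at every time",
           call. = FALSE)
    }
    df <- dplyr::arrange(df, .data$time, .data$vertex)
    wss <- matrix(df$wss, nrow = nv)
    return(new_wss_field(mesh, tt, wss))
  }
  if (all(c("vertex", "tawss") %in% names(df))) {
    if (nrow(df) != nv || !setequal(df$vertex, seq_len(nv))) {
      stop("CSV metrics are incomplete: expected one row per vertex",
           call. = FALSE)
    }
    df <- dplyr::arrange(df, .data$vertex)
    return(new_wss_metrics(mesh, df$tawss,
                           if ("osi" %in% names(df)) df$osi else NULL))
  }
  stop("CSV must hold (vertex, time, wss) or (vertex, tawss[, osi])",
       call. = FALSE)
}

check_wss_units <- function(declared) {
  if (is.null(declared) || is.na(declared) || !nzchar(declared)) {
    stop("WSS units are undeclared; declare `", WSS_UNITS,
         "` in the file or pass `units`", call. = FALSE)
  }
  norm <- gsub("[^a-z0-9]", "", tolower(declared))
  if (norm != gsub("[^a-z0-9]", "", tolower(WSS_UNITS))) {
    stop("unsupported WSS units: ", declared, " (expected ", WSS_UNITS, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

new_wss_metrics <- function(mesh, tawss, osi = NULL) {
  stopifnot(length(tawss) == nrow(mesh$vertices))
  if (!is.null(osi)) stopifnot(length(osi) == length(tawss))
  structure(list(mesh = mesh, tawss = tawss, osi = osi),
            class = "coro_wss_metrics")
}

#' @export
print.coro_wss_metrics <- function(x, ...) {
  cat(sprintf("<coro_wss_metrics> %d vertices; TAWSS%s\n",
              length(x$tawss), if (is.null(x$osi)) " only" else " + OSI"))
  invisible(x)
}
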