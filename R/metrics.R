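#' Fractional flow reserve from a network solution
#'
#' FFR is the time-averaged pressure at a node distal to the lesion divided
#' by the time-averaged aortic-root pressure over the final (periodic) cycle.
#' Values near 1 indicate no flow-limiting lesion; the conventional ischemia
#' threshold is 0.8. With the default resting calibration this is the
#' resting mean Pd/Pa ratio; pass a calibration with `hyperemia = TRUE` for
#' the classical hyperemic index.
#'
#' @param trace A `coro_solution`.
#' @param distal_node Name of the distal measurement point: an internal
#'   junction (e.g. `"LM_out"`), an outlet branch name (e.g. `"LAD"`, taken
#'   at its outlet interface), or a vessel name which is resolved to its
#'   distal node.
#' @param proximal_node Proximal reference node (default the aortic root).
#' @return FFR, dimensionless.
#' @examples
#' \donttest{
#' sol <- solve_transient(assemble_network(list(stenosis_spec("LAD", 0.5))),
#'                        n_cycles = 4, steps_per_cycle = 200)
#' compute_ffr(sol, "LAD")
#' }
#' @export
compute_ffr <- function(trace, distal_node, proximal_node = "root") {
  stopifnot(inherits(trace, "coro_solution"))
  pd <- cycle_mean(trace$time, resolve_pressure_series(trace, distal_node))
  pa <- cycle_mean(trace$time, resolve_pressure_series(trace, proximal_node))
  if (abs(pa) < .Machine$double.eps) {
    stop("mean proximal pressure is zero", call. = FALSE)
  }
  pd / pa
}

resolve_pressure_series <- function(trace, node) {
  np <- trace$node_pressures
  op <- trace$outlet_pressures
  if (node %in% colnames(np)) return(np[, node])
  if (node %in% colnames(op)) return(op[, node])
  alt <- paste0(node, "_out")
  if (alt %in% colnames(np)) return(np[, alt])
  stop("unknown node: ", node, call. = FALSE)
}

# distal measurement point for a vessel in a solved network
vessel_distal_node <- function(trace, vessel) {
  if (vessel %in% trace$network$internal) paste0(vessel, "_out") else vessel
}

new_wss_field <- function(mesh, time, wss) {
  stopifnot(inherits(mesh, "coro_mesh"))
  if (!is.matrix(wss) || nrow(wss) != nrow(mesh$vertices) ||
      ncol(wss) != length(time)) {
    stop("`wss` must be an n_vertices x n_times matrix", call. = FALSE)
  }
  if (any(!is.finite(wss))) stop("WSS values must be finite", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  structure(list(mesh = mesh, time = time, wss = wss),
            class = "coro_wss_field")
}

#' @export
print.coro_wss_field <- function(x, ...) {
  cat(sprintf("<coro_wss_field> %d vertices x %d times over [%g, %g] s\n",
              nrow(x$wss), ncol(x$wss), min(x$time), max(x$time)))
  invisible(x)
}

#' Quasi-steady wall shear stress field from a flow waveform
#'
#' Maps a flow waveform onto a vessel surface with the quasi-steady
#' Poiseuille reduction `tau(z, t) = 4 mu Q(t) / (pi r(z)^3)` (signed by the
#' flow direction). Each circumferential ring carries a uniform value -- for
#' eccentric meshes the same ring value is used, so azimuthal shear asymmetry
#' is outside this reduction.
#'
#' @param trace A `coro_solution` (with `vessel`), or a data frame with
#'   columns `time` and `flow`.
#' @param profile The vessel's `coro_profile`.
#' @param vessel Branch name, when `trace` is a solution.
#' @param mesh Optional prebuilt `coro_mesh` of `profile`.
#' @param n_circumferential Ring resolution used when `mesh` is built here.
#' @param time_stride Keep every `time_stride`-th sample of the trace.
#' @return A `coro_wss_field`.
#' @examples
#' prof <- stenosed_radius_profile(stenosis_spec("LM", 0.5), n_axial = 41)
#' qs <- data.frame(time = seq(0, 1, 0.01), flow = 2 + sin(2 * pi * seq(0, 1, 0.01)))
#' field <- wss_waveform_from_flow(qs, prof, n_circumferential = 16)
#' @export
wss_waveform_from_flow <- function(trace, profile, vessel = NULL, mesh = NULL,
                                   n_circumferential = 48, time_stride = 1) {
  if (inherits(trace, "coro_solution")) {
    if (is.null(vessel)) stop("`vessel` is required", call. = FALSE)
    tt <- trace$time
    q <- trace$flows[, vessel]
  } else {
    tt <- trace$time
    q <- trace$flow
  }
  if (time_stride > 1) {
    idx <- unique(c(seq(1, length(tt), by = time_stride), length(tt)))
    tt <- tt[idx]; q <- q[idx]
  }
  if (is.null(mesh)) mesh <- build_surface_mesh(profile, n_circumferential)
  r <- profile$radius[mesh$ring]
  if (any(r <= 0)) stop("radius must be positive everywhere", call. = FALSE)
  mu <- blood_properties()$mu
  wss <- outer(4 * mu / (pi * r^3), q)
  new_wss_field(mesh, tt, wss)
}

trapezoid_weights <- function(time) {
  dt <- diff(time)
  c(dt[1] / 2, (dt[-1] + dt[-length(dt)]) / 2, dt[length(dt)] / 2)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per-vertex time average of the WSS magnitude over one cycle,
#' `TAWSS = (1/T) integral |tau(t)| dt`, by trapezoidal quadrature on the
#' field's time grid.
#'
#' @param field A `coro_wss_field`.
#' @return Numeric vector, one value per vertex (dyne/cm^2).
#' @export
tawss <- function(field) {
  stopifnot(inherits(field, "coro_wss_field"))
  w <- trapezoid_weights(field$time)
  T_ <- field$time[length(field$time)] - field$time[1]
  as.vector(abs(field$wss) %*% w) / T_
}

#' Oscillatory shear index (OSI)
#'
#' Per-vertex `OSI = 0.5 * (1 - |integral tau dt| / integral |tau| dt)`,
#' in \[0, 0.5\]: 0 for unidirectional shear, 0.5 for fully reversing shear.
#' Vertices with identically zero shear get OSI 0 by convention.
#'
#' @param field A `coro_wss_field`.
#' @return Numeric vector, one value per vertex.
#' @export
osi <- function(field) {
  stopifnot(inherits(field, "coro_wss_field"))
  w <- trapezoid_weights(field$time)
  num <- abs(as.vector(field$wss %*% w))
  den <- as.vector(abs(field$wss) %*% w)
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

#' Per-vertex WSS metrics table
#'
#' @param field A `coro_wss_field`.
#' @return Tibble with `vertex`, `z`, `tawss`, `osi`.
#' @export
wss_metrics <- function(field) {
  tibble::tibble(
    vertex = seq_len(nrow(field$wss)),
    z = field$mesh$z,
    tawss = tawss(field),
    osi = osi(field)
  )
}

#' Abnormal-area quantification
#'
#' Sums the surface area of triangles whose vertex-mean metric is abnormal:
#' TAWSS strictly below `low_tawss` (atherosclerosis-prone low shear), TAWSS
#' strictly above `high_tawss` (injury-prone high shear), or OSI strictly
#' above `high_osi` (disturbed, direction-reversing flow). The default
#' thresholds are 4 and 40 dyne/cm^2 and 0.2.
#'
#' @param x A `coro_wss_field`, or a `coro_wss_metrics` container with
#'   precomputed per-vertex metrics (as returned by [import_wss_field()] for
#'   files holding TAWSS/OSI arrays). When OSI is unavailable the OSI area is
#'   `NA`.
#' @param low_tawss,high_tawss,high_osi Classification thresholds.
#' @return One-row tibble: `area_low_tawss`, `area_high_tawss`,
#'   `area_high_osi`, `total_area` (cm^2).
#' @examples
#' syn <- make_synthetic_wss_field(
#'   tibble::tibble(z_min = 1, z_max = 4, mean = 2, amplitude = 0),
#'   n_axial = 51, n_circumferential = 16, n_time = 20
#' )
#' abnormal_areas(syn$field)
#' @export
abnormal_areas <- function(x, low_tawss = 4, high_tawss = 40, high_osi = 0.2) {
  if (inherits(x, "coro_wss_field")) {
    mesh <- x$mesh
    ta <- tawss(x)
    os <- osi(x)
  } else if (inherits(x, "coro_wss_metrics")) {
    mesh <- x$mesh
    ta <- x$tawss
    os <- x$osi
    if (is.null(ta)) stop("metrics container lacks TAWSS", call. = FALSE)
  } else {
    stop("`x` must be a WSS field or a WSS metrics container", call. = FALSE)
  }
  tri <- mesh$triangles
  tri_mean <- function(v) (v[tri[, 1]] + v[tri[, 2]] + v[tri[, 3]]) / 3
  ta_m <- tri_mean(ta)
  tibble::tibble(
    area_low_tawss = sum(mesh$patch_area[ta_m < low_tawss]),
    area_high_tawss = sum(mesh$patch_area[ta_m > high_tawss]),
    area_high_osi = if (is.null(os)) NA_real_ else
      sum(mesh$patch_area[tri_mean(os) > high_osi]),
    total_area = sum(mesh$patch_area)
  )
}
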