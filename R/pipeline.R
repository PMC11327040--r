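#' Solver and post-processing settings for sweep runs
#'
#' The run protocol defaults: 12 cardiac cycles of 500 steps each with a 1%
#' cycle-to-cycle pressure-change tolerance; surface meshes of 121 axial x 32
#' circumferential vertices with every 5th time sample for the quasi-steady
#' WSS post-processing; stenosis loss coefficients Kv = 1, Kt = 1.52.
#'
#' @param n_cycles,steps_per_cycle,tol Passed to [solve_transient()].
#' @param n_axial,n_circumferential,wss_stride WSS post-processing mesh and
#'   time resolution.
#' @param Kv,Kt Stenosis loss coefficients, passed to [stenosis_element()].
#' @param inertance Include vessel inertances.
#' @return A list of class `coro_settings`.
#' @export
sweep_settings <- function(n_cycles = 12, steps_per_cycle = 500, tol = 0.01,
                           n_axial = 121, n_circumferential = 32,
                           wss_stride = 5, Kv = 1, Kt = 1.52,
                           inertance = FALSE) {
  structure(
    list(n_cycles = n_cycles, steps_per_cycle = steps_per_cycle, tol = tol,
         n_axial = n_axial, n_circumferential = n_circumferential,
         wss_stride = wss_stride, Kv = Kv, Kt = Kt, inertance = inertance),
    class = "coro_settings"
  )
}

#' Run a single simulation case
#'
#' Builds the (possibly stenosed) network, integrates it to the final cycle,
#' and computes the case metrics: FFR at the stenosed vessel's distal node,
#' LCA (LM inlet) and RCA peak-flow metrics, and abnormal TAWSS/OSI areas of
#' the quasi-steady WSS field on the stenosed vessel's surface.
#'
#' @param vessel Vessel name, or `"none"` for the normal model.
#' @param ds Degree of diameter stenosis.
#' @param eccentricity `"concentric"` or `"eccentric"`.
#' @param calibration A `coro_calibration`.
#' @param settings A `coro_settings`.
#' @param keep_trace Keep the full `coro_solution` in the result.
#' @return List of class `coro_case` with `record` (one-row tibble) and,
#'   optionally, `trace`.
#' @examples
#' \donttest{
#' case <- run_case("LM", 0.5, settings = sweep_settings(n_cycles = 4,
#'                                                       steps_per_cycle = 200))
#' case$record
#' }
#' @export
run_case <- function(vessel = "none", ds = 0, eccentricity = "concentric",
                     calibration = default_calibration(),
                     settings = sweep_settings(),
                     keep_trace = FALSE) {
  stopifnot(inherits(settings, "coro_settings"))
  stenosed <- !identical(vessel, "none") && ds > 0
  stenoses <- if (stenosed) {
    list(stenosis_spec(vessel, ds = ds, eccentricity = eccentricity))
  } else list()

  net <- assemble_network(stenoses, calibration,
                          inertance = settings$inertance,
                          Kv = settings$Kv, Kt = settings$Kt)
  sol <- solve_transient(net, n_cycles = settings$n_cycles,
                         steps_per_cycle = settings$steps_per_cycle,
                         tol = settings$tol)

  lca <- peak_flow_metrics(sol, "LM")
  rca <- peak_flow_metrics(sol, "RCA")

  if (stenosed) {
    ffr <- compute_ffr(sol, vessel_distal_node(sol, vessel))
    prof <- stenosed_radius_profile(
      stenosis_spec(vessel, ds = ds, eccentricity = eccentricity),
      n_axial = settings$n_axial
    )
    field <- wss_waveform_from_flow(
      sol, prof, vessel = vessel,
      n_circumferential = settings$n_circumferential,
      time_stride = settings$wss_stride
    )
    areas <- abnormal_areas(field)
  } else {
    ffr <- min(vapply(c("LM", "LAD", "LCX", "RCA"), function(v) {
      compute_ffr(sol, vessel_distal_node(sol, v))
    }, numeric(1)))
    areas <- tibble::tibble(area_low_tawss = NA_real_,
                            area_high_tawss = NA_real_,
                            area_high_osi = NA_real_)
  }

  record <- tibble::tibble(
    vessel = vessel, ds = ds,
    eccentricity = if (stenosed) eccentricity else "concentric",
    ffr = ffr,
    lca_peak = lca$peak_value,
    lca_peak_time = lca$peak_time,
    rca_peak = rca$peak_value,
    rca_first_peak = rca$first_peak_value,
    rca_n_peaks = rca$n_peaks,
    area_low_tawss = areas$area_low_tawss,
    area_high_tawss = areas$area_high_tawss,
    area_high_osi = areas$area_high_osi,
    convergence = if (nrow(sol$convergence))
      sol$convergence$metric[nrow(sol$convergence)] else NA_real_,
    converged = sol$converged,
    provenance = case_provenance(vessel, ds, eccentricity, settings)
  )
  out <- list(record = record)
  if (keep_trace) out$trace <- sol
  structure(out, class = "coro_case")
}

case_provenance <- function(vessel, ds, eccentricity, settings) {
  paste0(vessel, ":", ds, ":", substr(eccentricity, 1, 3), ":",
         settings$n_cycles, "x", settings$steps_per_cycle,
         ":Kv", settings$Kv, ":Kt", settings$Kt)
}

#' Run the stenosis sweep
#'
#' Runs every configuration (see [make_sweep_fixture()]), computes percentage
#' reductions of the LCA peak and the RCA first characteristic peak relative
#' to the normal baseline, and optionally writes the result tables
#' (`ffr_by_ds.csv`, `peak_reductions.csv`, `abnormal_areas_by_ds.csv`) to a
#' directory. The pipeline is fully deterministic: rerunning the same
#' configurations reproduces the tables byte for byte.
#'
#' @param configs Tibble from [make_sweep_fixture()] (columns `vessel`, `ds`,
#'   `eccentricity`).
#' @param calibration A `coro_calibration`.
#' @param settings A `coro_settings`.
#' @param out_dir Optional output directory for the CSV tables.
#' @param progress Print one line per case.
#' @return A tibble of class `coro_sweep`, one row per case. Failed cases are
#'   kept with `error` filled in and metrics `NA`.
#' @examples
#' \donttest{
#' sweep <- run_sweep(make_sweep_fixture(ds_levels = 0.7, vessels = "LM",
#'                                       eccentricities = "concentric"),
#'                    settings = sweep_settings(n_cycles = 4,
#'                                              steps_per_cycle = 200))
#' }
#' @export
run_sweep <- function(configs,
                      calibration = default_calibration(),
                      settings = sweep_settings(),
                      out_dir = NULL,
                      progress = FALSE) {
  configs <- tibble::as_tibble(configs)
  if (nrow(configs) == 0L) stop("`configs` is empty", call. = FALSE)
  need <- c("vessel", "ds", "eccentricity")
  if (!all(need %in% names(configs))) {
    stop("`configs` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }

  records <- purrr::pmap(
    configs[need],
    function(vessel, ds, eccentricity) {
      rec <- tryCatch(
        run_case(vessel, ds, eccentricity, calibration, settings)$record,
        error = function(e) {
          tibble::tibble(vessel = vessel, ds = ds,
                         eccentricity = eccentricity,
                         error = conditionMessage(e))
        }
      )
      if (progress) {
        message(sprintf("case %s ds=%.1f %s: %s", vessel, ds, eccentricity,
                        if ("error" %in% names(rec)) "FAILED" else "ok"))
      }
      rec
    }
  )
  res <- dplyr::bind_rows(records)
  if (!"error" %in% names(res)) res$error <- NA_character_

  normal <- dplyr::filter(res, .data$vessel == "none" | .data$ds == 0)
  if (nrow(normal) >= 1L && !is.na(normal$lca_peak[1])) {
    res$lca_peak_reduction <- percent_reduction(normal$lca_peak[1],
                                                res$lca_peak)
    res$rca_first_peak_reduction <-
      percent_reduction(normal$rca_first_peak[1], res$rca_first_peak)
  } else {
    res$lca_peak_reduction <- NA_real_
    res$rca_first_peak_reduction <- NA_real_
  }
  class(res) <- c("coro_sweep", class(res))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(
      dplyr::select(res, "vessel", "ds", "eccentricity", "ffr"),
      file.path(out_dir, "ffr_by_ds.csv")
    )
    readr::write_csv(
      dplyr::select(res, "vessel", "ds", "eccentricity",
                    "lca_peak", "lca_peak_reduction",
                    "rca_first_peak", "rca_first_peak_reduction"),
      file.path(out_dir, "peak_reductions.csv")
    )
    readr::write_csv(
      dplyr::select(res, "vessel", "ds", "eccentricity",
                    "area_low_tawss", "area_high_tawss", "area_high_osi"),
      file.path(out_dir, "abnormal_areas_by_ds.csv")
    )
    manifest <- list(
      n_cases = nrow(res),
      n_failed = sum(!is.na(res$error)),
      all_converged = all(res$converged, na.rm = TRUE),
      max_convergence_metric = suppressWarnings(max(res$convergence,
                                                    na.rm = TRUE)),
      settings = unclass(settings)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' One-row summary of a sweep
#'
#' @param x A `coro_sweep`.
#' @param ... Unused.
#' @return Tibble with case counts, convergence and the minimum FFR of the
#'   mild (DS <= 0.5) cases.
#' @export
glance.coro_sweep <- function(x, ...) {
  mild <- dplyr::filter(x, .data$ds > 0, .data$ds <= 0.5)
  tibble::tibble(
    n_cases = nrow(x),
    n_failed = sum(!is.na(x$error)),
    all_converged = all(x$converged, na.rm = TRUE),
    min_mild_ffr = if (nrow(mild)) min(mild$ffr, na.rm = TRUE) else NA_real_
  )
}
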