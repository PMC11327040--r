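#' Synthetic wall-shear-stress field with analytically known metrics
#'
#' Builds a straight-cylinder surface mesh carrying, in prescribed axial
#' bands, the signed WSS waveform `tau(t) = mean + amplitude * cos(2 pi t/T)`.
#' For this family the cycle metrics have closed forms: with `m = |mean|` and
#' `a = amplitude`,
#' `TAWSS = m` and `OSI = 0` when `m >= a`, otherwise
#' `TAWSS = (2/pi) * (sqrt(a^2 - m^2) + m * asin(m/a))` and
#' `OSI = 0.5 * (1 - m / TAWSS)`. Vertices outside every band carry the
#' uniform mid-range `background` stress (default 20 dyne/cm^2,
#' unidirectional), which triggers none of the abnormal-area thresholds.
#'
#' The returned ground truth gives each band's analytic TAWSS/OSI and lateral
#' area (`2 pi r * span`), plus the analytic abnormal-area totals at the
#' standard thresholds, so the metrics engine can be checked against known
#' values.
#'
#' @param bands A data frame with columns `z_min`, `z_max` (cm), `mean`,
#'   `amplitude` (dyne/cm^2). Bands must not overlap.
#' @param radius,length Cylinder dimensions, cm.
#' @param n_axial,n_circumferential Mesh resolution.
#' @param n_time Number of time steps per cycle.
#' @param period Cycle period, s.
#' @param background Background stress level, dyne/cm^2.
#' @param thresholds Thresholds used for the analytic abnormal areas, as in
#'   [abnormal_areas()].
#' @return List with `field` (a `coro_wss_field`), `band_truth` (tibble with
#'   analytic per-band metrics and areas) and `area_truth` (one-row tibble of
#'   analytic abnormal-area totals, cm^2).
#' @examples
#' syn <- make_synthetic_wss_field(
#'   tibble::tibble(z_min = 1, z_max = 4, mean = 2, amplitude = 0)
#' )
#' syn$area_truth
#' @export
make_synthetic_wss_field <- function(bands,
                                     radius = 0.5,
                                     length = 10,
                                     n_axial = 401,
                                     n_circumferential = 48,
                                     n_time = 40,
                                     period = 1.0,
                                     background = 20,
                                     thresholds = list(low_tawss = 4,
                                                       high_tawss = 40,
                                                       high_osi = 0.2)) {
  bands <- tibble::as_tibble(bands)
  req <- c("z_min", "z_max", "mean", "amplitude")
  if (!all(req %in% names(bands))) {
    stop("`bands` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(bands$z_max <= bands$z_min) ||
      any(bands$z_min < 0) || any(bands$z_max > length)) {
    stop("band spans must be increasing and inside [0, length]", call. = FALSE)
  }
  if (nrow(bands) > 1) {
    o <- order(bands$z_min)
    if (any(bands$z_min[o][-1] < bands$z_max[o][-nrow(bands)])) {
      stop("bands must not overlap", call. = FALSE)
    }
  }

  vspec <- vessel_spec("LM", reference_diameter = 2 * radius,
                       segment_length = length,
                       stenosis_site_length = min(length / 2, 2 * radius))
  profile <- stenosed_radius_profile(stenosis_spec(vspec, ds = 0),
                                     n_axial = n_axial)
  mesh <- build_surface_mesh(profile, n_circumferential)

  tgrid <- seq(0, period, length.out = n_time + 1)
  cosw <- cos(2 * pi * tgrid / period)
  nv <- nrow(mesh$vertices)
  wss <- matrix(background, nv, length(tgrid))
  band_of <- rep(0L, nv)
  for (i in seq_len(nrow(bands))) {
    in_band <- mesh$z >= bands$z_min[i] & mesh$z <= bands$z_max[i]
    band_of[in_band] <- i
    wss[in_band, ] <- matrix(bands$mean[i] + bands$amplitude[i] * cosw,
                             sum(in_band), length(tgrid), byrow = TRUE)
  }

  field <- new_wss_field(mesh, tgrid, wss)

  # ground-truth band areas use the axial span actually representable on the
  # mesh: the range of vertex rings falling inside the band (identical to the
  # requested span whenever band edges coincide with mesh rings)
  snapped_span <- vapply(seq_len(nrow(bands)), function(i) {
    zs <- mesh$z[band_of == i]
    if (length(zs) < 2) 0 else max(zs) - min(zs)
  }, numeric(1))
  truth <- dplyr::mutate(
    bands,
    tawss = mean_abs_biased_cosine(abs(.data$mean), abs(.data$amplitude)),
    osi = ifelse(.data$tawss > 0,
                 0.5 * (1 - abs(.data$mean) / .data$tawss), 0),
    area = 2 * pi * radius * snapped_span
  )
  area_truth <- tibble::tibble(
    area_low_tawss = sum(truth$area[truth$tawss < thresholds$low_tawss]),
    area_high_tawss = sum(truth$area[truth$tawss > thresholds$high_tawss]),
    area_high_osi = sum(truth$area[truth$osi > thresholds$high_osi])
  )
  list(field = field, band_truth = truth, area_truth = area_truth)
}

# closed-form cycle mean of |m + a cos(theta)| (m, a >= 0)
mean_abs_biased_cosine <- function(m, a) {
  ifelse(m >= a, m,
         (2 / pi) * (sqrt(pmax(a^2 - m^2, 0)) + m * asin(ifelse(a > 0, m / a, 0))))
}

#' Run configurations for the stenosis sweep
#'
#' Enumerates fully specified run configurations for every requested vessel x
#' DS x eccentricity combination, plus (by default) the single normal
#' (stenosis-free) baseline. The full default sweep is 4 vessels x 7 DS
#' levels x 2 eccentricities + 1 normal = 57 configurations.
#'
#' @param ds_levels DS fractions, each in (0, 0.7]; multiples of 0.1 in the
#'   standard sweep.
#' @param vessels Character vector of vessel names.
#' @param eccentricities Subset of `c("concentric", "eccentric")`.
#' @param include_normal Include the stenosis-free baseline row.
#' @return A tibble of class `coro_configs` with columns `case`, `vessel`,
#'   `ds`, `eccentricity`; the normal baseline has `vessel = "none"`,
#'   `ds = 0`.
#' @examples
#' nrow(make_sweep_fixture())
#' @export
make_sweep_fixture <- function(ds_levels = seq(0.1, 0.7, by = 0.1),
                               vessels = c("LM", "LAD", "LCX", "RCA"),
                               eccentricities = c("concentric", "eccentric"),
                               include_normal = TRUE) {
  known <- vessel_table()$name
  if (length(vessels) == 0) stop("`vessels` must be non-empty", call. = FALSE)
  if (!all(vessels %in% known)) {
    stop("unknown vessel(s): ",
         paste(setdiff(vessels, known), collapse = ", "), call. = FALSE)
  }
  if (!all(eccentricities %in% c("concentric", "eccentric"))) {
    stop("unknown eccentricity", call. = FALSE)
  }
  ds_levels <- ds_levels[ds_levels > 0]
  if (any(ds_levels > 0.7 + 1e-12)) {
    stop("`ds_levels` must lie in (0, 0.7]", call. = FALSE)
  }
  grid <- tidyr::expand_grid(vessel = vessels, ds = ds_levels,
                             eccentricity = eccentricities)
  if (include_normal) {
    grid <- dplyr::bind_rows(
      tibble::tibble(vessel = "none", ds = 0, eccentricity = "concentric"),
      grid
    )
  }
  out <- dplyr::mutate(grid, case = dplyr::row_number(), .before = 1)
  class(out) <- c("coro_configs", class(out))
  out
}
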