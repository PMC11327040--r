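#' Reference dimensions of the four main coronary arteries
#'
#' Returns the healthy (reference) lumen diameter, the lesion (stenosis site)
#' length -- about 1.3 times the reference diameter, as used for low-grade
#' lesions -- and the default modelled segment length for the left main (LM),
#' left anterior descending (LAD), left circumflex (LCX) and right coronary
#' artery (RCA).
#'
#' Lesion lengths and reference diameters are the standard parametric-lesion
#' values (LM 0.7/0.50, LAD 0.62/0.44, LCX 0.5/0.36, RCA 0.63/0.45 cm).
#' Segment lengths beyond the lesion are typical-anatomy defaults and can be
#' overridden through [vessel_spec()].
#'
#' @return A tibble with columns `name`, `reference_diameter` (cm),
#'   `stenosis_site_length` (cm) and `segment_length` (cm).
#' @examples
#' vessel_table()
#' @export
vessel_table <- function() {
  tibble::tibble(
    name = c("LM", "LAD", "LCX", "RCA"),
    reference_diameter = c(0.50, 0.44, 0.36, 0.45),
    stenosis_site_length = c(0.70, 0.62, 0.50, 0.63),
    segment_length = c(1.0, 10.0, 8.0, 10.0)
  )
}

#' Specify a coronary vessel
#'
#' @param name One of `"LM"`, `"LAD"`, `"LCX"`, `"RCA"`.
#' @param reference_diameter Healthy lumen diameter, cm. Defaults to the
#'   value in [vessel_table()].
#' @param segment_length Total modelled vessel length, cm.
#' @param stenosis_site_length Lesion length, cm.
#' @return An object of class `coro_vessel` (a named list).
#' @examples
#' vessel_spec("LM")
#' @export
vessel_spec <- function(name,
                        reference_diameter = NULL,
                        segment_length = NULL,
                        stenosis_site_length = NULL) {
  tab <- vessel_table()
  if (!is.character(name) || length(name) != 1L || !name %in% tab$name) {
    stop("`name` must be one of ", paste(tab$name, collapse = ", "),
         call. = FALSE)
  }
  row <- tab[tab$name == name, ]
  spec <- list(
    name = name,
    reference_diameter = reference_diameter %||% row$reference_diameter,
    segment_length = segment_length %||% row$segment_length,
    stenosis_site_length = stenosis_site_length %||% row$stenosis_site_length
  )
  if (spec$reference_diameter <= 0) {
    stop("`reference_diameter` must be positive", call. = FALSE)
  }
  if (spec$stenosis_site_length <= 0) {
    stop("`stenosis_site_length` must be positive", call. = FALSE)
  }
  if (spec$stenosis_site_length > spec$segment_length) {
    stop("`stenosis_site_length` must not exceed `segment_length`",
         call. = FALSE)
  }
  structure(spec, class = "coro_vessel")
}

#' Specify a stenosis on a vessel
#'
#' A lesion is described by its degree of diameter stenosis `ds` (DS; the
#' fractional reduction of lumen diameter, so 50% DS halves the diameter and
#' quarters the area) and its shape type: `"concentric"` (axisymmetric) or
#' `"eccentric"` (plaque on one wall, lumen centre displaced until the lumen
#' is tangent to the healthy wall at the throat). The stenotic lumen cross
#' section is a perfect circle in both cases.
#'
#' @param vessel A `coro_vessel` from [vessel_spec()], or a vessel name.
#' @param ds Degree of diameter stenosis, a fraction in \[0, 0.7\].
#' @param eccentricity `"concentric"` or `"eccentric"`.
#' @return An object of class `coro_stenosis`.
#' @examples
#' stenosis_spec("LM", ds = 0.5)
#' @export
stenosis_spec <- function(vessel, ds = 0, eccentricity = c("concentric", "eccentric")) {
  if (is.character(vessel)) vessel <- vessel_spec(vessel)
  stopifnot(inherits(vessel, "coro_vessel"))
  eccentricity <- match.arg(eccentricity)
  if (!is.numeric(ds) || length(ds) != 1L || is.na(ds) || ds < 0 || ds >= 1) {
    stop("`ds` must be a single fraction in [0, 1)", call. = FALSE)
  }
  if (ds > 0.7 + 1e-12) {
    stop("`ds` above 0.7 is outside the supported lesion range", call. = FALSE)
  }
  structure(
    list(vessel = vessel, ds = ds, eccentricity = eccentricity),
    class = "coro_stenosis"
  )
}

#' Throat diameter and area of a stenosis
#'
#' The throat diameter is `reference_diameter * (1 - ds)` and the throat area
#' is `pi/4 * diameter^2`; the throat-to-normal area ratio is therefore
#' `(1 - ds)^2` exactly.
#'
#' @param spec A `coro_stenosis` from [stenosis_spec()].
#' @return A one-row tibble with `vessel`, `ds`, `diameter` (cm) and
#'   `area` (cm^2).
#' @examples
#' throat_metrics(stenosis_spec("LM", ds = 0.5))
#' @export
throat_metrics <- function(spec) {
  stopifnot(inherits(spec, "coro_stenosis"))
  d <- spec$vessel$reference_diameter * (1 - spec$ds)
  tibble::tibble(
    vessel = spec$vessel$name,
    ds = spec$ds,
    diameter = d,
    area = pi / 4 * d^2
  )
}

#' Throat metrics for a grid of vessels and stenosis degrees
#'
#' Convenience wrapper evaluating [throat_metrics()] over every combination of
#' the requested vessels and DS levels.
#'
#' @param vessels Character vector of vessel names.
#' @param ds_levels Numeric vector of DS fractions.
#' @return A tibble with one row per vessel x DS combination.
#' @examples
#' throat_table(ds_levels = c(0, 0.5))
#' @export
throat_table <- function(vessels = vessel_table()$name,
                         ds_levels = seq(0, 0.7, by = 0.1)) {
  grid <- tidyr::expand_grid(vessel = vessels, ds = ds_levels)
  purrr::pmap_dfr(grid, function(vessel, ds) {
    throat_metrics(stenosis_spec(vessel, ds = ds))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x
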