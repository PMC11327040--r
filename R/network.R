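#' Reduced-order stenosis loss element
#'
#' Empirical two-term (viscous + turbulent/expansion) pressure-loss law for a
#' constriction, standing in for the full three-dimensional stenosis flow:
#' \deqn{\Delta P = K_v \frac{8 \mu L_s}{\pi r_t^4} Q
#'       + K_t \frac{\rho}{2}\left(\frac{1}{A_s} - \frac{1}{A_0}\right)^2 Q |Q|}
#' with throat radius/area `r_t`/`A_s`, reference area `A_0` and lesion
#' length `L_s`. With `Kv = 1` the viscous term is exactly the Poiseuille
#' resistance of the throat over the lesion length, so the law reduces to
#' Poiseuille when `As = A0`; `Kt = 1.52` is the classical empirical
#' expansion-loss coefficient. The law is odd in `Q`, so reverse flow is
#' handled naturally.
#'
#' @param spec A `coro_stenosis`.
#' @param Kv,Kt Dimensionless loss coefficients.
#' @return An object of class `coro_sten_element`.
#' @examples
#' stenosis_element(stenosis_spec("LM", 0.7))
#' @export
stenosis_element <- function(spec, Kv = 1, Kt = 1.52) {
  stopifnot(inherits(spec, "coro_stenosis"))
  bp <- blood_properties()
  v <- spec$vessel
  r0 <- v$reference_diameter / 2
  rt <- r0 * (1 - spec$ds)
  if (rt <= 0) stop("throat area must be positive", call. = FALSE)
  A0 <- pi * r0^2
  As <- pi * rt^2
  structure(
    list(
      vessel = v$name,
      Kv = Kv, Kt = Kt,
      A0 = A0, As = As,
      lesion_length = v$stenosis_site_length,
      R_visc = Kv * 8 * bp$mu * v$stenosis_site_length / (pi * rt^4),
      k_turb = Kt * bp$rho / 2 * (1 / As - 1 / A0)^2
    ),
    class = "coro_sten_element"
  )
}

#' Pressure drop across a stenosis element
#'
#' @param elem A `coro_sten_element`.
#' @param Q Flow, cm^3/s (vectorised).
#' @return Pressure drop, dyne/cm^2.
#' @examples
#' stenosis_pressure_drop(stenosis_element(stenosis_spec("LM", 0.7)), 1)
#' @export
stenosis_pressure_drop <- function(elem, Q) {
  stopifnot(inherits(elem, "coro_sten_element"))
  elem$R_visc * Q + elem$k_turb * Q * abs(Q)
}

# derivative of the loss law wrt Q (for the Newton Jacobian)
stenosis_dpdq <- function(elem, Q) {
  elem$R_visc + 2 * elem$k_turb * abs(Q)
}

#' Poiseuille resistance and inertance of a vessel segment
#'
#' `R = 8 mu L / (pi r^4)`, `L_inert = rho L / A`, both from the healthy
#' reference radius of the segment.
#'
#' @param vessel A `coro_vessel`.
#' @return Named list with `R` (dyne.s/cm^5) and `L_inert` (dyne.s^2/cm^5).
#' @export
vessel_element <- function(vessel) {
  stopifnot(inherits(vessel, "coro_vessel"))
  bp <- blood_properties()
  r0 <- vessel$reference_diameter / 2
  list(
    R = 8 * bp$mu * vessel$segment_length / (pi * r0^4),
    L_inert = bp$rho * vessel$segment_length / (pi * r0^2)
  )
}

#' Build a lumped vessel network from a branch table
#'
#' Low-level constructor used by [assemble_network()] and by toy test
#' networks. Each branch runs from `parent` ("root" or the name of another
#' branch, meaning that branch's distal node) to either an internal junction
#' (if other branches list it as parent) or its outlet boundary model.
#' Junctions enforce a common pressure and exact flow conservation.
#'
#' @param branches Tibble with columns `name`, `parent`, `R` (dyne.s/cm^5),
#'   `L_inert` (dyne.s^2/cm^5), and list-columns `sten`
#'   (`coro_sten_element` or `NULL`) and `outlet` (`coro_outlet` or `NULL`).
#' @param inlet A `coro_waveform` tibble or a function of time giving the
#'   prescribed root inflow, cm^3/s.
#' @param period Cardiac period, s.
#' @return An object of class `coro_network`.
#' @export
network_from_branches <- function(branches, inlet, period = 1.0) {
  branches <- tibble::as_tibble(branches)
  need <- c("name", "parent", "R", "L_inert", "sten", "outlet")
  if (!all(need %in% names(branches))) {
    stop("`branches` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(branches$name)) {
    stop("branch names must be unique", call. = FALSE)
  }
  bad <- setdiff(branches$parent, c("root", branches$name))
  if (length(bad)) {
    stop("unknown parent(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  internal <- branches$name[branches$name %in% branches$parent]
  leaves <- setdiff(branches$name, internal)
  no_outlet <- vapply(branches$outlet, is.null, logical(1))
  if (any(branches$name %in% leaves & no_outlet)) {
    stop("every terminal branch needs an outlet model", call. = FALSE)
  }
  if (any(branches$name %in% internal & !no_outlet)) {
    stop("internal branches cannot carry an outlet model", call. = FALSE)
  }
  if (!any(branches$parent == "root")) {
    stop("network must be attached to the root", call. = FALSE)
  }
  if (is.data.frame(inlet)) inlet <- waveform_function(inlet)
  stopifnot(is.function(inlet))
  structure(
    list(
      branches = branches,
      nodes = c("root",
                if (length(internal)) paste0(internal, "_out")),
      internal = internal,
      inlet = inlet,
      period = period
    ),
    class = "coro_network"
  )
}

#' Assemble the coronary tree as a transient 0D network
#'
#' Builds the branch-free (simplified) coronary network: aortic root ->
#' aortic Windkessel outlet, LM and RCA; LM -> LAD and LCX; every coronary
#' outlet carries the intramyocardial-pressure coronary circuit. Each vessel
#' is a Poiseuille resistance (optionally with inertance) computed from its
#' healthy reference radius, in series with at most one stenosis element.
#' At `ds = 0` no stenosis element is created, so the healthy network is
#' reproduced exactly.
#'
#' @param stenoses List of `coro_stenosis` objects (at most one per vessel);
#'   empty list for the normal model.
#' @param calibration A `coro_calibration` from [default_calibration()].
#' @param inlet A `coro_waveform` or function of time; defaults to
#'   [make_inlet_waveform()] at the calibration's cardiac output and period.
#' @param inertance Include vessel inertances (`rho L / A`); off by default
#'   (the network is resistive-capacitive, matching the outlet circuits).
#' @param Kv,Kt Stenosis loss coefficients, passed to [stenosis_element()].
#' @return A `coro_network`.
#' @examples
#' net <- assemble_network(list(stenosis_spec("LM", 0.5)))
#' @export
assemble_network <- function(stenoses = list(),
                             calibration = default_calibration(),
                             inlet = NULL,
                             inertance = FALSE,
                             Kv = 1, Kt = 1.52) {
  stopifnot(inherits(calibration, "coro_calibration"))
  if (inherits(stenoses, "coro_stenosis")) stenoses <- list(stenoses)
  sten_vessels <- vapply(stenoses, function(s) s$vessel$name, character(1))
  if (anyDuplicated(sten_vessels)) {
    stop("at most one stenosis per vessel", call. = FALSE)
  }
  known <- vessel_table()$name
  if (length(sten_vessels) && !all(sten_vessels %in% known)) {
    stop("stenosis on unknown vessel: ",
         paste(setdiff(sten_vessels, known), collapse = ", "), call. = FALSE)
  }

  sten_for <- function(nm) {
    i <- match(nm, sten_vessels)
    if (is.na(i) || stenoses[[i]]$ds == 0) return(NULL)
    stenosis_element(stenoses[[i]], Kv = Kv, Kt = Kt)
  }
  velem <- function(nm) {
    i <- match(nm, sten_vessels)
    v <- if (is.na(i)) vessel_spec(nm) else stenoses[[i]]$vessel
    e <- vessel_element(v)
    if (!inertance) e$L_inert <- 0
    e
  }

  mk <- function(nm, parent, outlet_name) {
    e <- if (nm == "AO") list(R = 0, L_inert = 0) else velem(nm)
    tibble::tibble(
      name = nm, parent = parent, R = e$R, L_inert = e$L_inert,
      sten = list(if (nm == "AO") NULL else sten_for(nm)),
      outlet = list(if (is.na(outlet_name)) NULL
                    else build_outlet(calibration, outlet_name))
    )
  }
  branches <- dplyr::bind_rows(
    mk("AO", "root", "AO"),
    mk("LM", "root", NA),
    mk("LAD", "LM", "LAD"),
    mk("LCX", "LM", "LCX"),
    mk("RCA", "root", "RCA")
  )
  if (is.null(inlet)) {
    inlet <- make_inlet_waveform(
      mean_flow = calibration$cardiac_output,
      period = calibration$period,
      systolic_fraction = calibration$systolic_fraction
    )
  }
  net <- network_from_branches(branches, inlet, period = calibration$period)
  net$calibration <- calibration
  net
}

#' @export
print.coro_network <- function(x, ...) {
  ns <- sum(!vapply(x$branches$sten, is.null, logical(1)))
  cat(sprintf("<coro_network> %d branches, %d junction node(s), %d stenosis element(s)\n",
              nrow(x$branches), length(x$internal), ns))
  invisible(x)
}

#' Tidy a network into its branch table
#'
#' @param x A `coro_network`.
#' @param ... Unused.
#' @return Tibble with one row per branch: name, parent, resistance,
#'   inertance, stenosis presence and area ratio, outlet type.
#' @export
tidy.coro_network <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$branches, "name", "parent", "R", "L_inert"),
    has_stenosis = !vapply(x$branches$sten, is.null, logical(1)),
    area_ratio = vapply(x$branches$sten, function(s) {
      if (is.null(s)) NA_real_ else s$As / s$A0
    }, numeric(1)),
    outlet_type = vapply(x$branches$outlet, function(o) {
      if (is.null(o)) NA_character_ else o$type
    }, character(1))
  )
}

#' Percentage reduction of a scalar relative to a reference
#'
#' `100 * (reference - test) / reference`; negative values mean an increase.
#'
#' @param reference Reference (normal-model) value, must be positive.
#' @param test Comparison value.
#' @return Percent reduction.
#' @examples
#' percent_reduction(100, 91.9)
#' @export
percent_reduction <- function(reference, test) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("`reference` must be positive", call. = FALSE)
  }
  100 * (reference - test) / reference
}
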