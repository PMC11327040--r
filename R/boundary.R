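#' Total outlet resistance from mean pressure and flow
#'
#' The total resistance a downstream bed must present so that it carries flow
#' `Qaorta` at mean pressure `Pmean`: `Rd + Rp = Pmean / Qaorta`.
#'
#' @param Pmean Mean pressure, dyne/cm^2.
#' @param Qaorta Mean flow through the outlet, cm^3/s.
#' @return Resistance, dyne.s/cm^5.
#' @examples
#' total_outlet_resistance(mmHg_to_dyne(93), 83)
#' @export
total_outlet_resistance <- function(Pmean, Qaorta) {
  if (!is.numeric(Qaorta) || Qaorta <= 0) {
    stop("`Qaorta` must be positive", call. = FALSE)
  }
  Pmean / Qaorta
}

#' Split a total resistance into a three-element Windkessel (RCR)
#'
#' Splits `R_total` into a distal (capillary/venous) resistance
#' `Rd = distal_fraction * R_total` and a proximal (viscous arterial)
#' resistance `Rp = R_total - Rd`. The default split is Rd:Rp = 0.91:0.09.
#'
#' @param R_total Total resistance, dyne.s/cm^5.
#' @param distal_fraction Fraction of `R_total` assigned to `Rd`, in (0, 1).
#' @param C Windkessel compliance, cm^5/dyne (default 0.001).
#' @param Pref Distal reference pressure, dyne/cm^2.
#' @return An object of class `coro_rcr` with fields `Rp`, `Rd`, `C`, `Pref`.
#' @examples
#' split_rcr(1000)
#' @export
split_rcr <- function(R_total, distal_fraction = 0.91, C = 0.001, Pref = 0) {
  if (distal_fraction <= 0 || distal_fraction >= 1) {
    stop("`distal_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (R_total <= 0) {
    stop("`R_total` must be positive", call. = FALSE)
  }
  if (C <= 0) stop("`C` must be positive", call. = FALSE)
  Rd <- distal_fraction * R_total
  structure(
    list(Rp = R_total - Rd, Rd = Rd, C = C, Pref = Pref, type = "rcr"),
    class = c("coro_rcr", "coro_outlet")
  )
}

#' Split a total compliance into microcirculatory and myocardial parts
#'
#' `Ca = ca_fraction * C_total`, `Cim = C_total - Ca`. The default ratio is
#' Ca:Cim = 0.11:0.89 and the default total is 0.001 cm^5/dyne.
#'
#' @param C_total Total compliance, cm^5/dyne.
#' @param ca_fraction Fraction assigned to the microcirculatory compliance.
#' @return Named list with `Ca` and `Cim` (cm^5/dyne).
#' @examples
#' split_compliance()
#' @export
split_compliance <- function(C_total = 0.001, ca_fraction = 0.11) {
  if (!is.numeric(C_total) || C_total <= 0) {
    stop("`C_total` must be positive", call. = FALSE)
  }
  if (ca_fraction <= 0 || ca_fraction >= 1) {
    stop("`ca_fraction` must be in (0, 1)", call. = FALSE)
  }
  list(Ca = ca_fraction * C_total, Cim = C_total - ca_fraction * C_total)
}

#' Allocate per-outlet total resistances from target mean flows
#'
#' Each outlet's total resistance is inversely proportional to its target mean
#' flow, anchored so the outlet carries its target flow at the mean pressure:
#' `R_i = Pmean / Q_i` (so R_cor : R_aorta = Q_aorta : Q_cor).
#'
#' @param Pmean Mean pressure, dyne/cm^2.
#' @param Q_targets Named numeric vector of target mean flows, cm^3/s.
#' @return Tibble with `outlet`, `Q_target` and `R_total`.
#' @examples
#' allocate_outlet_resistances(mmHg_to_dyne(93), c(LAD = 1.4, LCX = 0.8))
#' @export
allocate_outlet_resistances <- function(Pmean, Q_targets) {
  if (any(!is.finite(Q_targets)) || any(Q_targets <= 0)) {
    stop("all target flows must be positive", call. = FALSE)
  }
  tibble::tibble(
    outlet = names(Q_targets) %||% as.character(seq_along(Q_targets)),
    Q_target = unname(Q_targets),
    R_total = Pmean / unname(Q_targets)
  )
}

#' Coronary lumped-parameter outlet circuit
#'
#' The coronary outlet circuit: inlet -- Ra -- node a (Ca to ground) --
#' Ra_micro -- node b (Cim referenced to the intramyocardial pressure
#' Pim(t)) -- Rv -- venous reference Pv. During systole Pim compresses the
#' myocardial compliance, impeding inflow; in diastole the released
#' compliance draws flow -- the mechanism behind the diastolic-dominant left
#' coronary waveform and the two-peak right coronary waveform.
#'
#' @param R_total Total outlet resistance (Ra + Ra_micro + Rv), dyne.s/cm^5.
#' @param C_total Total outlet compliance (Ca + Cim), cm^5/dyne.
#' @param splits Length-3 numeric, fractions of `R_total` assigned to
#'   Ra, Ra_micro, Rv. Default 0.32, 0.52, 0.16.
#' @param ca_fraction Fraction of `C_total` assigned to Ca (default 0.11).
#' @param pim Function of time (s) returning the intramyocardial pressure
#'   (dyne/cm^2), periodic over the cardiac cycle.
#' @param Pv Venous reference pressure, dyne/cm^2.
#' @return An object of class `coro_lpn`.
#' @examples
#' lpn <- coronary_lpn(9e4, 4e-5, pim = make_pim_waveform(peak = mmHg_to_dyne(120)))
#' @export
coronary_lpn <- function(R_total, C_total,
                         splits = c(0.32, 0.52, 0.16),
                         ca_fraction = 0.11,
                         pim = function(t) rep(0, length(t)),
                         Pv = 0) {
  if (R_total <= 0 || C_total <= 0) {
    stop("`R_total` and `C_total` must be positive", call. = FALSE)
  }
  if (length(splits) != 3L || any(splits <= 0) ||
      abs(sum(splits) - 1) > 1e-9) {
    stop("`splits` must be three positive fractions summing to 1",
         call. = FALSE)
  }
  if (!is.function(pim)) {
    stop("`pim` must be a function of time (see make_pim_waveform)",
         call. = FALSE)
  }
  cc <- split_compliance(C_total, ca_fraction)
  structure(
    list(
      Ra = splits[1] * R_total,
      Ra_micro = splits[2] * R_total,
      Rv = splits[3] * R_total,
      Ca = cc$Ca,
      Cim = cc$Cim,
      pim = pim,
      Pv = Pv,
      type = "coronary"
    ),
    class = c("coro_lpn", "coro_outlet")
  )
}

#' State derivative of the RCR Windkessel
#'
#' The single stored state is the pressure `Pc` across the compliance:
#' `dPc/dt = (Q_in - (Pc - Pref) / Rd) / C`; the interface pressure seen by
#' the network is `P_in = Pc + Q_in * Rp`.
#'
#' @param model A `coro_rcr`.
#' @param state Numeric, current `Pc` (dyne/cm^2).
#' @param Q_in Inflow, cm^3/s.
#' @param t Time, s (unused; kept for a uniform signature).
#' @return Named list with `dstate` and interface pressure `P_in`.
#' @export
rcr_state_derivative <- function(model, state, Q_in, t = 0) {
  stopifnot(inherits(model, "coro_rcr"))
  dPc <- (Q_in - (state[1] - model$Pref) / model$Rd) / model$C
  list(dstate = dPc, P_in = state[1] + Q_in * model$Rp)
}

#' State derivatives of the coronary outlet circuit
#'
#' States are `Pa` (pressure at node a, across Ca) and `u = Pb - Pim(t)`
#' (pressure across the myocardial compliance Cim, which is referenced to the
#' intramyocardial pressure). Charge balance gives
#' `dPa/dt = (Q_in - (Pa - Pb)/Ra_micro) / Ca` and
#' `du/dt = ((Pa - Pb)/Ra_micro - (Pb - Pv)/Rv) / Cim` with
#' `Pb = u + Pim(t)`. Interface pressure `P_in = Pa + Q_in * Ra`.
#'
#' @param model A `coro_lpn`.
#' @param state Numeric length 2: `c(Pa, u)`.
#' @param Q_in Inflow, cm^3/s.
#' @param t Time, s.
#' @return Named list with `dstate` (length 2), `P_in` and `Pb`.
#' @export
coronary_lpn_state_derivative <- function(model, state, Q_in, t = 0) {
  stopifnot(inherits(model, "coro_lpn"))
  Pb <- state[2] + model$pim(t)
  q_ab <- (state[1] - Pb) / model$Ra_micro
  dPa <- (Q_in - q_ab) / model$Ca
  du <- (q_ab - (Pb - model$Pv) / model$Rv) / model$Cim
  list(dstate = c(dPa, du), P_in = state[1] + Q_in * model$Ra, Pb = Pb)
}

#' @export
print.coro_rcr <- function(x, ...) {
  cat(sprintf("<coro_rcr> Rp %.4g  Rd %.4g dyne.s/cm^5, C %.3g cm^5/dyne\n",
              x$Rp, x$Rd, x$C))
  invisible(x)
}

#' @export
print.coro_lpn <- function(x, ...) {
  cat(sprintf(
    "<coro_lpn> Ra %.4g  Ra_micro %.4g  Rv %.4g dyne.s/cm^5, Ca %.3g  Cim %.3g cm^5/dyne\n",
    x$Ra, x$Ra_micro, x$Rv, x$Ca, x$Cim))
  invisible(x)
}

#' Tidy an outlet circuit into a parameter tibble
#'
#' @param x A `coro_rcr` or `coro_lpn`.
#' @param ... Unused.
#' @return Tibble of parameter names, values and units.
#' @export
tidy.coro_outlet <- function(x, ...) {
  keep <- vapply(x, is.numeric, logical(1))
  vals <- unlist(x[keep])
  unit <- ifelse(grepl("^R", names(vals)), "dyne.s/cm^5",
          ifelse(grepl("^C", names(vals)), "cm^5/dyne", "dyne/cm^2"))
  tibble::tibble(term = names(vals), value = unname(vals), unit = unit)
}
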