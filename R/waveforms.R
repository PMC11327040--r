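#' Synthetic pulsatile aortic inflow waveform
#'
#' Piecewise-sinusoidal template of the aortic root flow: a systolic half-sine
#' ejection, a brief early-diastolic reverse dip at valve closure, and a low
#' diastolic hump (the residual diastolic run-off, which in the root is
#' essentially the coronary inflow). The sampled series is renormalised so its
#' discrete periodic (trapezoidal) time-mean equals `mean_flow` exactly.
#'
#' The defaults describe a resting healthy adult: cardiac output 5 L/min
#' (mean 83.33 cm^3/s), period 1 s, systolic fraction 0.35.
#'
#' @param mean_flow Target time-mean flow, cm^3/s.
#' @param period Cardiac period, s.
#' @param systolic_fraction Fraction of the cycle spent in ejection.
#' @param reverse_flow_fraction Amplitude of the valve-closure reverse dip as
#'   a fraction of the ejection peak; 0 disables backflow.
#' @param diastolic_fraction Amplitude of the diastolic hump as a fraction of
#'   the ejection peak.
#' @param n_steps Number of time steps per cycle; the series has
#'   `n_steps + 1` samples with identical first and last values.
#' @param noise_sd Standard deviation of optional smooth multiplicative
#'   noise; 0 (default) gives the deterministic template.
#' @param seed Integer seed used only when `noise_sd > 0`.
#' @return A tibble of class `coro_waveform` with columns `time` (s) and
#'   `flow` (cm^3/s); attributes record the spec.
#' @examples
#' w <- make_inlet_waveform()
#' mean(w$flow[-nrow(w)])
#' @export
make_inlet_waveform <- function(mean_flow = 5000 / 60,
                                period = 1.0,
                                systolic_fraction = 0.35,
                                reverse_flow_fraction = 0.05,
                                diastolic_fraction = 0.04,
                                n_steps = 500,
                                noise_sd = 0,
                                seed = 1L) {
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("`systolic_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (reverse_flow_fraction < 0 || reverse_flow_fraction >= 1) {
    stop("`reverse_flow_fraction` must be in [0, 1)", call. = FALSE)
  }
  t <- seq(0, period, length.out = n_steps + 1)
  ts <- systolic_fraction * period
  tr <- 0.05 * period               # reverse-dip duration
  t1 <- ts + tr

  shape <- numeric(length(t))
  sys <- t <= ts
  shape[sys] <- sin(pi * t[sys] / ts)
  dip <- t > ts & t <= t1
  shape[dip] <- -reverse_flow_fraction * sin(pi * (t[dip] - ts) / tr)
  dia <- t > t1
  shape[dia] <- diastolic_fraction * sin(pi * (t[dia] - t1) / (period - t1))^2

  if (noise_sd > 0) {
    rs <- local({ set.seed(seed); stats::rnorm(8) })
    wig <- rowSums(sapply(1:4, function(k) {
      rs[k] * sin(2 * pi * k * t / period) + rs[k + 4] * cos(2 * pi * k * t / period)
    })) / 4
    shape <- shape * (1 + noise_sd * wig)
    shape[length(shape)] <- shape[1]  # keep periodic closure
  }

  # renormalise: periodic trapezoid mean equals mean_flow exactly
  m0 <- mean(shape[-length(shape)])
  if (abs(m0) < .Machine$double.eps) {
    stop("degenerate waveform shape: zero mean before renormalisation",
         call. = FALSE)
  }
  flow <- shape * (mean_flow / m0)

  out <- tibble::tibble(time = t, flow = flow)
  class(out) <- c("coro_waveform", class(out))
  attr(out, "period") <- period
  attr(out, "mean_flow") <- mean_flow
  out
}

#' Periodic interpolator for a sampled waveform
#'
#' @param waveform A `coro_waveform` tibble (columns `time`, `flow`).
#' @return A function of time (s), periodic with the waveform's period.
#' @export
waveform_function <- function(waveform) {
  period <- attr(waveform, "period") %||% max(waveform$time)
  f <- stats::approxfun(waveform$time, waveform$flow, rule = 2)
  function(t) f(t %% period)
}

#' Intramyocardial pressure pulse
#'
#' Ventricular-contraction pressure waveform loading the myocardial
#' compliance of the coronary outlet circuit: a C1 sine-squared pulse, zero
#' throughout diastole, `Pim(t) = peak * sin(pi (t + lead) / (t_sys + lead))^2`
#' for `-lead <= t <= t_sys` (periodically wrapped) with
#' `t_sys = systolic_fraction * period`. Its integral over one cycle is
#' `peak * (t_sys + lead) / 2`.
#'
#' The `lead` models isovolumic contraction: ventricular (and hence
#' intramyocardial) pressure starts rising some tens of milliseconds before
#' the aortic valve opens, so with the cycle clock starting at ejection the
#' pulse leads the inflow waveform. This timing is what makes the simulated
#' left coronary flow systolically impeded and diastolic-dominant.
#'
#' @param period Cardiac period, s.
#' @param peak Peak intramyocardial pressure, dyne/cm^2 (120 mmHg is the
#'   left-ventricular default; right-sided outlets are conventionally scaled
#'   to right-ventricular pressure, about 0.2 of that).
#' @param systolic_fraction Fraction of the cycle spent in ejection.
#' @param lead Isovolumic-contraction lead time, s (0 starts the pulse at
#'   ejection onset).
#' @return A function of time (s), periodic, of class `coro_pim`.
#' @examples
#' pim <- make_pim_waveform(peak = mmHg_to_dyne(120))
#' pim(0.175)
#' @export
make_pim_waveform <- function(period = 1.0,
                              peak = mmHg_to_dyne(120),
                              systolic_fraction = 0.35,
                              lead = 0) {
  if (peak < 0) stop("`peak` must be non-negative", call. = FALSE)
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  if (lead < 0 || lead >= period * (1 - systolic_fraction)) {
    stop("`lead` must be non-negative and shorter than diastole",
         call. = FALSE)
  }
  ts <- systolic_fraction * period
  f <- function(t) {
    phase <- (t + lead) %% period
    ifelse(phase <= ts + lead,
           peak * sin(pi * phase / (ts + lead))^2, 0)
  }
  structure(f, class = c("coro_pim", "function"),
            period = period, peak = peak,
            systolic_fraction = systolic_fraction, lead = lead)
}
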