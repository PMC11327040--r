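# CGS unit conventions used throughout:
#   length cm, time s, pressure dyne/cm^2, flow cm^3/s,
#   resistance dyne.s/cm^5, compliance cm^5/dyne.

#' Unit conversion between mmHg and dyne/cm^2
#'
#' All internal pressures are in CGS units (dyne/cm^2); clinical pressures are
#' quoted in mmHg. 1 mmHg = 1333.22 dyne/cm^2.
#'
#' @param x Numeric vector of pressures.
#' @return Numeric vector in the target unit.
#' @examples
#' mmHg_to_dyne(93)
#' dyne_to_mmHg(mmHg_to_dyne(93))
#' @export
mmHg_to_dyne <- function(x) x * 1333.22

#' @rdname mmHg_to_dyne
#' @export
dyne_to_mmHg <- function(x) x / 1333.22

#' Physical constants of the blood model
#'
#' Blood is treated as a homogeneous Newtonian fluid with dynamic viscosity
#' 0.04 dyne.s/cm^2 and density 1.06 g/mL.
#'
#' @return Named list with `mu` (dyne.s/cm^2) and `rho` (g/cm^3).
#' @export
blood_properties <- function() {
  list(mu = 0.04, rho = 1.06)
}
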