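#' Default hemodynamic calibration for the coronary network
#'
#' Literature resting values for a healthy adult, all overridable: cardiac
#' output 5 L/min, mean aortic pressure 93 mmHg, total coronary flow 4% of
#' cardiac output, LCA:RCA split 2:1, LAD:LCX split by Murray's law on the
#' reference diameters (flow proportional to d^3). Outlet circuits follow the
#' standard ratios: Rd:Rp = 0.91:0.09 for the aortic Windkessel (compliance
#' 0.001 cm^5/dyne), coronary resistance split Ra:Ra_micro:Rv =
#' 0.32:0.52:0.16, coronary compliance split Ca:Cim = 0.11:0.89 with a total
#' coronary-bed compliance of 1e-4 cm^5/dyne distributed over outlets by flow
#' share. Intramyocardial pressure peaks at left-ventricular pressure
#' (120 mmHg) for left-coronary outlets and right-ventricular pressure
#' (scale 0.2) for the RCA.
#'
#' @param cardiac_output Mean aortic inflow, cm^3/s.
#' @param Pmean Mean aortic pressure, dyne/cm^2.
#' @param coronary_fraction Coronary share of cardiac output.
#' @param lca_fraction LCA share of total coronary flow.
#' @param lad_fraction LAD share of LCA flow; `NULL` uses Murray's law.
#' @param period Cardiac period, s.
#' @param systolic_fraction Systolic fraction of the cycle.
#' @param aortic_C Aortic Windkessel compliance, cm^5/dyne.
#' @param rcr_distal_fraction Distal fraction of the aortic Windkessel.
#' @param coronary_C_total Total coronary-bed compliance, cm^5/dyne.
#' @param coronary_ca_fraction Microcirculatory fraction of each outlet's
#'   compliance.
#' @param coronary_r_splits Ra, Ra_micro, Rv fractions of each outlet's total
#'   resistance.
#' @param pim_peak Peak left intramyocardial pressure, dyne/cm^2.
#' @param pim_rca_scale Scale applied to `pim_peak` for the RCA outlet.
#' @param pim_lead Isovolumic-contraction lead of the intramyocardial pulse
#'   relative to ejection onset, s (see [make_pim_waveform()]).
#' @param Pv,Pref Venous / distal reference pressures, dyne/cm^2.
#' @param hyperemia If `TRUE`, scale the coronary microcirculatory
#'   resistances by `hyperemia_factor` (adenosine-type hyperemic state used
#'   for classical FFR; the resting state is the default).
#' @param hyperemia_factor Multiplier on Ra_micro under hyperemia.
#' @return A list of class `coro_calibration` including the per-outlet target
#'   flows, total resistances and compliances.
#' @examples
#' cal <- default_calibration()
#' cal$outlets
#' @export
default_calibration <- function(cardiac_output = 5000 / 60,
                                Pmean = mmHg_to_dyne(93),
                                coronary_fraction = 0.04,
                                lca_fraction = 2 / 3,
                                lad_fraction = NULL,
                                period = 1.0,
                                systolic_fraction = 0.35,
                                aortic_C = 0.001,
                                rcr_distal_fraction = 0.91,
                                coronary_C_total = 1e-4,
                                coronary_ca_fraction = 0.11,
                                coronary_r_splits = c(0.32, 0.52, 0.16),
                                pim_peak = mmHg_to_dyne(120),
                                pim_rca_scale = 0.2,
                                pim_lead = 0.08,
                                Pv = 0,
                                Pref = 0,
                                hyperemia = FALSE,
                                hyperemia_factor = 0.24) {
  stopifnot(cardiac_output > 0, Pmean > 0,
            coronary_fraction > 0, coronary_fraction < 1,
            lca_fraction > 0, lca_fraction < 1)
  tab <- vessel_table()
  if (is.null(lad_fraction)) {
    d3 <- tab$reference_diameter[match(c("LAD", "LCX"), tab$name)]^3
    lad_fraction <- d3[1] / sum(d3)
  }
  Q_cor <- coronary_fraction * cardiac_output
  Q_lca <- lca_fraction * Q_cor
  q <- c(
    AO = cardiac_output - Q_cor,
    LAD = lad_fraction * Q_lca,
    LCX = (1 - lad_fraction) * Q_lca,
    RCA = Q_cor - Q_lca
  )
  alloc <- allocate_outlet_resistances(Pmean, q)
  cor_names <- c("LAD", "LCX", "RCA")
  c_share <- coronary_C_total * q[cor_names] / Q_cor

  structure(
    list(
      cardiac_output = cardiac_output,
      Pmean = Pmean,
      period = period,
      systolic_fraction = systolic_fraction,
      outlets = dplyr::mutate(
        alloc,
        C_total = c(aortic_C, unname(c_share)),
        pim_peak = c(0, pim_peak, pim_peak, pim_peak * pim_rca_scale)
      ),
      rcr_distal_fraction = rcr_distal_fraction,
      coronary_ca_fraction = coronary_ca_fraction,
      coronary_r_splits = coronary_r_splits,
      pim_lead = pim_lead,
      Pv = Pv,
      Pref = Pref,
      hyperemia = hyperemia,
      hyperemia_factor = hyperemia_factor
    ),
    class = "coro_calibration"
  )
}

# Build the outlet model for one named outlet of the calibrated tree.
build_outlet <- function(cal, name) {
  row <- cal$outlets[cal$outlets$outlet == name, ]
  if (nrow(row) != 1L) stop("unknown outlet: ", name, call. = FALSE)
  if (name == "AO") {
    split_rcr(row$R_total, cal$rcr_distal_fraction, C = row$C_total,
              Pref = cal$Pref)
  } else {
    lpn <- coronary_lpn(
      row$R_total, row$C_total,
      splits = cal$coronary_r_splits,
      ca_fraction = cal$coronary_ca_fraction,
      pim = make_pim_waveform(cal$period, row$pim_peak,
                              cal$systolic_fraction,
                              lead = cal$pim_lead %||% 0),
      Pv = cal$Pv
    )
    if (isTRUE(cal$hyperemia)) {
      lpn$Ra_micro <- lpn$Ra_micro * cal$hyperemia_factor
    }
    lpn
  }
}
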