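#' Plot the flow waveforms of a network solution
#'
#' One panel per branch, flow over the final cycle.
#'
#' @param object A `coro_solution`.
#' @param branches Branch names to show; default all.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coro_solution <- function(object, branches = NULL, ...) {
  df <- dplyr::filter(tidy(object), .data$kind == "flow")
  if (!is.null(branches)) df <- dplyr::filter(df, .data$series %in% branches)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "flow [cm³/s]",
                  title = "Final-cycle flow waveforms")
}

#' Plot sweep results against degree of stenosis
#'
#' @param object A `coro_sweep`.
#' @param metric `"ffr"`, `"areas"` or `"peaks"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coro_sweep <- function(object, metric = c("ffr", "areas", "peaks"),
                                ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(tibble::as_tibble(object), .data$ds > 0)
  base <- function(d, y, ylab) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$ds, y = {{ y }},
                                    colour = .data$vessel,
                                    linetype = .data$eccentricity)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "degree of stenosis", y = ylab)
  }
  switch(metric,
    ffr = base(df, .data$ffr, "resting mean Pd/Pa"),
    peaks = base(df, .data$lca_peak_reduction, "LCA peak-flow reduction [%]"),
    areas = {
      long <- tidyr::pivot_longer(
        df, dplyr::all_of(c("area_low_tawss", "area_high_tawss",
                            "area_high_osi")),
        names_to = "measure", values_to = "area"
      )
      ggplot2::ggplot(long, ggplot2::aes(x = .data$ds, y = .data$area,
                                         colour = .data$vessel,
                                         linetype = .data$eccentricity)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~measure, scales = "free_y") +
        ggplot2::labs(x = "degree of stenosis", y = "area [cm²]")
    }
  )
}

#' Plot a WSS field's axial TAWSS profile
#'
#' Ring-averaged TAWSS along the vessel axis.
#'
#' @param object A `coro_wss_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coro_wss_field <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(wss_metrics(object), .data$z),
    tawss = mean(.data$tawss), osi = mean(.data$osi), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$tawss)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(4, 40), linetype = "dashed") +
    ggplot2::labs(x = "axial position [cm]", y = "TAWSS [dyne/cm²]")
}
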