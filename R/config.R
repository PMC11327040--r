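# YAML run configuration: geometry overrides, calibration overrides, solver
# settings and the case list, in the same vocabulary as the function
# arguments. Units are CGS; pressures may be given in mmHg with the `_mmHg`
# suffix.

#' Write a sweep run configuration to YAML
#'
#' @param path Output path.
#' @param configs Case tibble (see [make_sweep_fixture()]).
#' @param calibration_args Named list of overrides for
#'   [default_calibration()].
#' @param settings_args Named list of overrides for [sweep_settings()].
#' @return `path`, invisibly.
#' @export
write_run_config <- function(path, configs = make_sweep_fixture(),
                             calibration_args = list(),
                             settings_args = list()) {
  yaml::write_yaml(
    list(
      cases = lapply(seq_len(nrow(configs)), function(i) {
        list(vessel = configs$vessel[i], ds = configs$ds[i],
             eccentricity = configs$eccentricity[i])
      }),
      calibration = calibration_args,
      settings = settings_args
    ),
    path
  )
  invisible(path)
}

#' Read a sweep run configuration from YAML
#'
#' @param path YAML file written by [write_run_config()] (or by hand in the
#'   same layout).
#' @return List with `configs` (tibble), `calibration`
#'   (`coro_calibration`) and `settings` (`coro_settings`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cal_args <- y$calibration %||% list()
  for (nm in names(cal_args)) {
    if (grepl("_mmHg$", nm)) {
      cal_args[[sub("_mmHg$", "", nm)]] <- mmHg_to_dyne(cal_args[[nm]])
      cal_args[[nm]] <- NULL
    }
  }
  configs <- if (length(y$cases)) {
    dplyr::bind_rows(lapply(y$cases, tibble::as_tibble))
  } else {
    make_sweep_fixture()
  }
  list(
    configs = configs,
    calibration = do.call(default_calibration, cal_args),
    settings = do.call(sweep_settings, y$settings %||% list())
  )
}
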