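# Shared fixtures. The full sweep is expensive, so it is run once per test
# session and reused by the pipeline and acceptance tests.

sweep_cache <- new.env(parent = emptyenv())

full_sweep <- function() {
  if (is.null(sweep_cache$result)) {
    sweep_cache$result <- run_sweep(make_sweep_fixture(),
                                    settings = sweep_settings())
  }
  sweep_cache$result
}

# small two-outlet network (one Windkessel, one coronary circuit) used for
# solver oracle tests; parameters give cycle-scale time constants
toy_two_outlet_network <- function(pim_peak = 4e4, inlet = NULL) {
  rcr <- split_rcr(1000, distal_fraction = 0.9, C = 1e-3)
  lpn <- coronary_lpn(5000, 1e-4,
                      pim = make_pim_waveform(1, pim_peak, 0.35))
  branches <- tibble::tibble(
    name = c("b1", "b2"),
    parent = c("root", "root"),
    R = c(50, 200),
    L_inert = c(0, 0),
    sten = list(NULL, NULL),
    outlet = list(rcr, lpn)
  )
  if (is.null(inlet)) inlet <- function(t) 5 + 2 * sin(2 * pi * t)
  network_from_branches(branches, inlet, period = 1)
}

# printed reference dimensions of the parametric lesions: per vessel, the
# throat diameter and area at each degree of stenosis, as published
printed_throat_table <- function() {
  tibble::tribble(
    ~vessel, ~ds, ~area, ~diameter,
    "LM", 0.0, "0.2", "0.5",
    "LM", 0.1, "0.159", "0.45",
    "LM", 0.2, "0.126", "0.4",
    "LM", 0.3, "0.096", "0.35",
    "LM", 0.4, "0.071", "0.3",
    "LM", 0.5, "0.049", "0.25",
    "LM", 0.6, "0.031", "0.2",
    "LM", 0.7, "0.018", "0.15",
    "LAD", 0.0, "0.15", "0.44",
    "LAD", 0.1, "0.123", "0.396",
    "LAD", 0.2, "0.097", "0.352",
    "LAD", 0.3, "0.075", "0.308",
    "LAD", 0.4, "0.055", "0.264",
    "LAD", 0.5, "0.038", "0.22",
    "LAD", 0.6, "0.024", "0.176",
    "LAD", 0.7, "0.014", "0.132",
    "LCX", 0.0, "0.1", "0.36",
    "LCX", 0.1, "0.082", "0.324",
    "LCX", 0.2, "0.065", "0.288",
    "LCX", 0.3, "0.05", "0.252",
    "LCX", 0.4, "0.037", "0.216",
    "LCX", 0.5, "0.025", "0.18",
    "LCX", 0.6, "0.016", "0.144",
    "LCX", 0.7, "0.009", "0.108",
    "RCA", 0.0, "0.16", "0.45",
    "RCA", 0.1, "0.129", "0.405",
    "RCA", 0.2, "0.102", "0.36",
    "RCA", 0.3, "0.078", "0.315",
    "RCA", 0.4, "0.057", "0.27",
    "RCA", 0.5, "0.04", "0.225",
    "RCA", 0.6, "0.025", "0.18",
    "RCA", 0.7, "0.014", "0.135"
  )
}

# number of decimals in a printed value
printed_decimals <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}
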