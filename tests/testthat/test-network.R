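test_that("stenosis pressure drop follows the two-term loss law", {
  # hand arithmetic for the LM lesion at 70% DS, Q = 1 cm^3/s
  mu <- 0.04; rho <- 1.06
  r0 <- 0.25; rt <- 0.25 * 0.3; Ls <- 0.7
  visc <- 8 * mu * Ls / (pi * rt^4)
  turb <- 1.52 * rho / 2 * (1 / (pi * rt^2) - 1 / (pi * r0^2))^2
  elem <- stenosis_element(stenosis_spec("LM", 0.7))
  expect_equal(stenosis_pressure_drop(elem, 1), visc + turb, tolerance = 1e-12)

  # no constriction: the turbulent term vanishes, Poiseuille remains
  open <- stenosis_element(stenosis_spec("LM", 0))
  expect_equal(open$k_turb, 0)
  expect_equal(stenosis_pressure_drop(open, 2),
               2 * 8 * mu * Ls / (pi * r0^4))

  # zero flow, zero drop; odd symmetry in Q
  expect_equal(stenosis_pressure_drop(elem, 0), 0)
  expect_equal(stenosis_pressure_drop(elem, -1.3),
               -stenosis_pressure_drop(elem, 1.3))
})

test_that("vessel elements use Poiseuille resistance and rho L / A inertance", {
  v <- vessel_spec("LCX")
  e <- vessel_element(v)
  expect_equal(e$R, 8 * 0.04 * 8 / (pi * 0.18^4))
  expect_equal(e$L_inert, 1.06 * 8 / (pi * 0.18^2))
})

test_that("network assembly builds the coronary tree with the requested lesions", {
  healthy <- assemble_network()
  tl <- tidy(healthy)
  expect_equal(nrow(tl), 5)
  expect_equal(sum(tl$has_stenosis), 0)
  expect_equal(healthy$internal, "LM")

  net <- assemble_network(list(stenosis_spec("LM", 0.5)))
  tl <- tidy(net)
  expect_equal(sum(tl$has_stenosis), 1)
  expect_equal(tl$area_ratio[tl$name == "LM"], 0.25)

  # ds = 0 adds no element, so the healthy network is recovered exactly
  none <- assemble_network(list(stenosis_spec("LAD", 0)))
  expect_equal(sum(tidy(none)$has_stenosis), 0)

  expect_error(
    assemble_network(list(stenosis_spec("LM", 0.3), stenosis_spec("LM", 0.5))),
    "one stenosis per vessel"
  )
})

test_that("branch tables are validated", {
  rcr <- split_rcr(1000)
  base <- tibble::tibble(
    name = "b1", parent = "root", R = 10, L_inert = 0,
    sten = list(NULL), outlet = list(rcr)
  )
  expect_s3_class(network_from_branches(base, function(t) 1), "coro_network")
  expect_error(
    network_from_branches(dplyr::mutate(base, outlet = list(NULL)),
                          function(t) 1),
    "outlet"
  )
  expect_error(
    network_from_branches(dplyr::mutate(base, parent = "nowhere"),
                          function(t) 1),
    "unknown parent"
  )
})

test_that("percent reduction is signed and guarded", {
  expect_equal(percent_reduction(100, 91.9), 8.1)
  expect_equal(percent_reduction(42, 42), 0)
  expect_equal(percent_reduction(50, 60), -20)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("peak metrics recover constructed maxima", {
  tt <- seq(0, 1, length.out = 501)
  sine <- data.frame(time = tt, flow = sin(2 * pi * tt))
  pm <- peak_flow_metrics(sine)
  expect_equal(pm$peak_time, 0.25, tolerance = 2e-3)
  expect_equal(pm$peak_value, 1, tolerance = 1e-4)

  two <- data.frame(time = tt,
                    flow = exp(-((tt - 0.2) / 0.05)^2) * 2 +
                           exp(-((tt - 0.6) / 0.08)^2) * 3)
  pm2 <- peak_flow_metrics(two)
  expect_equal(pm2$n_peaks, 2)
  expect_equal(pm2$first_peak_time, 0.2, tolerance = 2e-3)
  expect_equal(pm2$peak_time, 0.6, tolerance = 2e-3)

  flat <- data.frame(time = tt, flow = rep(1, length(tt)))
  expect_true(peak_flow_metrics(flat)$no_peak)
})
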