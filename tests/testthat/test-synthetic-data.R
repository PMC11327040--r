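test_that("inlet waveform hits the target mean exactly and is deterministic", {
  w <- make_inlet_waveform(mean_flow = 83, period = 1.0)
  expect_equal(mean(w$flow[-nrow(w)]), 83, tolerance = 1e-9)
  expect_equal(w$flow[1], w$flow[nrow(w)])

  # no reverse fraction, no backflow
  w0 <- make_inlet_waveform(reverse_flow_fraction = 0)
  expect_gte(min(w0$flow), 0)

  # deterministic: seeds do not matter without noise, and a fixed seed
  # reproduces the noisy series bit for bit
  expect_identical(make_inlet_waveform(seed = 1)$flow,
                   make_inlet_waveform(seed = 99)$flow)
  expect_identical(make_inlet_waveform(noise_sd = 0.05, seed = 7)$flow,
                   make_inlet_waveform(noise_sd = 0.05, seed = 7)$flow)
  expect_false(identical(make_inlet_waveform(noise_sd = 0.05, seed = 7)$flow,
                         make_inlet_waveform(noise_sd = 0.05, seed = 8)$flow))
  expect_error(make_inlet_waveform(systolic_fraction = 1.2), "\\(0, 1\\)")
})

test_that("intramyocardial pulse has the constructed peak and integral", {
  expect_equal(make_pim_waveform(peak = 0)(seq(0, 1, 0.01)), rep(0, 101))
  peak <- mmHg_to_dyne(120)
  pim <- make_pim_waveform(1, peak, 0.35)
  tt <- seq(0, 1, 1e-4)
  expect_equal(max(pim(tt)), peak, tolerance = 1e-6)
  expect_equal(pim(0.175), peak)            # mid-systole is the crest
  expect_true(all(pim(seq(0.36, 0.99, 0.01)) == 0))
  # integral of the sine-squared pulse is peak * t_sys / 2
  num <- mean(pim(seq(0, 1, length.out = 200001)[-200001]))
  expect_equal(num, peak * 0.35 / 2, tolerance = 1e-5)
  # with an isovolumic lead the pulse widens accordingly
  lead <- make_pim_waveform(1, peak, 0.35, lead = 0.08)
  expect_gt(lead(0.99), 0)                  # pre-systolic rise
  num2 <- mean(lead(seq(0, 1, length.out = 200001)[-200001]))
  expect_equal(num2, peak * (0.35 + 0.08) / 2, tolerance = 1e-5)
  expect_error(make_pim_waveform(peak = -1), "non-negative")
})

test_that("synthetic WSS fields carry their analytic ground truth", {
  bands <- tibble::tibble(
    z_min = c(1, 5), z_max = c(4, 6),
    mean = c(2, 0), amplitude = c(0, 10)
  )
  syn <- make_synthetic_wss_field(bands, radius = 0.5, length = 10,
                                  n_axial = 101, n_circumferential = 16,
                                  n_time = 40)
  # constant band: TAWSS equals the level, no oscillation
  expect_equal(syn$band_truth$tawss[1], 2)
  expect_equal(syn$band_truth$osi[1], 0)
  # zero-mean band: full reversal
  expect_equal(syn$band_truth$osi[2], 0.5)
  expect_equal(syn$band_truth$tawss[2], 10 * 2 / pi)
  expect_equal(syn$band_truth$area, 2 * pi * 0.5 * c(3, 1))
  expect_equal(syn$area_truth$area_low_tawss, 2 * pi * 0.5 * 3)
  expect_equal(syn$area_truth$area_high_osi, 2 * pi * 0.5 * 1)
  expect_error(
    make_synthetic_wss_field(tibble::tibble(z_min = c(1, 2), z_max = c(3, 4),
                                            mean = 1, amplitude = 0)),
    "overlap"
  )
})

test_that("sweep fixture enumerates the full study design", {
  full <- make_sweep_fixture()
  expect_equal(nrow(full), 4 * 7 * 2 + 1)
  expect_equal(sum(full$vessel == "none"), 1)
  expect_equal(nrow(make_sweep_fixture(ds_levels = 0)), 1)
  expect_error(make_sweep_fixture(vessels = character(0)), "non-empty")
  expect_error(make_sweep_fixture(vessels = "AORTA"), "unknown vessel")
  expect_error(make_sweep_fixture(ds_levels = 0.9), "0.7")
})
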