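make_uniform_field <- function(values_over_time, n_axial = 21, n_circ = 12,
                               radius = 0.25) {
  prof <- stenosed_radius_profile(
    stenosis_spec(vessel_spec("LM", reference_diameter = 2 * radius,
                              segment_length = 2, stenosis_site_length = 0.5),
                  ds = 0),
    n_axial = n_axial)
  mesh <- build_surface_mesh(prof, n_circ)
  tt <- seq(0, 1, length.out = length(values_over_time))
  wss <- matrix(values_over_time, nrow(mesh$vertices), length(tt),
                byrow = TRUE)
  coroflow:::new_wss_field(mesh, tt, wss)
}

test_that("FFR is the mean distal-to-aortic pressure ratio", {
  sol <- solve_transient(assemble_network(list(stenosis_spec("LM", 0.6))),
                         n_cycles = 6, steps_per_cycle = 250)
  ffr <- compute_ffr(sol, "LM_out")
  pd <- coroflow:::cycle_mean(sol$time, sol$node_pressures[, "LM_out"])
  pa <- coroflow:::cycle_mean(sol$time, sol$node_pressures[, "root"])
  expect_equal(ffr, pd / pa)
  expect_lt(ffr, 1)
  # vessel-name resolution points at the distal measurement plane
  expect_equal(compute_ffr(sol, "LM"), ffr)
  expect_error(compute_ffr(sol, "nowhere"), "unknown node")

  # equal constant pressures give exactly 1: synthetic two-node check
  fake <- sol
  fake$node_pressures[, "LM_out"] <- fake$node_pressures[, "root"]
  expect_equal(compute_ffr(fake, "LM_out"), 1)
  fake$node_pressures[, "LM_out"] <- 0.95 * fake$node_pressures[, "root"]
  expect_equal(compute_ffr(fake, "LM_out"), 0.95)
})

test_that("quasi-steady WSS follows the Poiseuille cubic-radius law", {
  prof <- stenosed_radius_profile(stenosis_spec("LM", 0.5), n_axial = 61)
  steady <- data.frame(time = seq(0, 1, 0.1), flow = 2)
  field <- wss_waveform_from_flow(steady, prof, n_circumferential = 12)
  mu <- 0.04
  r <- prof$radius[field$mesh$ring]
  expect_equal(field$wss[, 1], 4 * mu * 2 / (pi * r^3))
  # throat-to-healthy ratio is (1 - ds)^-3 = 8
  ta <- tawss(field)
  expect_equal(max(ta) / ta[1], 8, tolerance = 1e-9)

  # zero-mean sinusoidal flow has zero time-mean signed WSS everywhere
  tt <- seq(0, 1, length.out = 201)
  sym <- data.frame(time = tt, flow = sin(2 * pi * tt))
  f2 <- wss_waveform_from_flow(sym, prof, n_circumferential = 12)
  w <- coroflow:::trapezoid_weights(f2$time)
  expect_lt(max(abs(as.vector(f2$wss %*% w))), 1e-12)
})

test_that("TAWSS averages the magnitude with closed-form checks", {
  expect_equal(tawss(make_uniform_field(rep(10, 101))), rep(10, 21 * 12))
  square <- c(rep(10, 50), rep(-10, 50), 10)
  expect_equal(mean(tawss(make_uniform_field(square))), 10, tolerance = 0.02)
  tt <- seq(0, 1, length.out = 501)
  half_sine <- 7 * sin(pi * tt)
  expect_equal(mean(tawss(make_uniform_field(half_sine))), 2 * 7 / pi,
               tolerance = 1e-4)
})

test_that("OSI spans [0, 0.5] with the expected limits", {
  expect_equal(osi(make_uniform_field(rep(3, 41))), rep(0, 21 * 12))
  tt <- seq(0, 1, length.out = 401)
  expect_equal(mean(osi(make_uniform_field(5 * sin(2 * pi * tt)))), 0.5,
               tolerance = 1e-6)
  # partially reversing waveform against a dense quadrature oracle
  tau <- function(t) 0.5 + sin(2 * pi * t)
  dense <- seq(0, 1, length.out = 2e5 + 1)
  num <- abs(coroflow:::cycle_mean(dense, tau(dense)))
  den <- coroflow:::cycle_mean(dense, abs(tau(dense)))
  oracle <- 0.5 * (1 - num / den)
  got <- mean(osi(make_uniform_field(tau(seq(0, 1, length.out = 501)))))
  expect_equal(got, oracle, tolerance = 1e-4)
})

test_that("metric invariances hold on random fields", {
  set.seed(42)
  for (rep in 1:5) {
    vals <- stats::rnorm(301, mean = stats::runif(1, -2, 2), sd = 3)
    field <- make_uniform_field(vals, n_axial = 11, n_circ = 12)
    o <- osi(field)
    expect_true(all(o >= 0 & o <= 0.5))
    flipped <- field; flipped$wss <- -field$wss
    expect_equal(tawss(flipped), tawss(field))
    expect_equal(osi(flipped), o)
    reversed <- field; reversed$wss <- field$wss[, rev(seq_len(ncol(field$wss)))]
    expect_equal(osi(reversed), o, tolerance = 1e-12)
  }
})

test_that("abnormal areas classify by vertex mean with strict thresholds", {
  mid <- make_uniform_field(rep(20, 11))
  aa <- abnormal_areas(mid)
  expect_equal(aa$area_low_tawss, 0)
  expect_equal(aa$area_high_tawss, 0)
  expect_equal(aa$area_high_osi, 0)

  # uniform OSI above threshold flags the whole surface
  tt <- seq(0, 1, length.out = 101)
  osc <- make_uniform_field(3 * sin(2 * pi * tt))
  aa2 <- abnormal_areas(osc)
  expect_equal(aa2$area_high_osi, aa2$total_area)

  # boundary values are not abnormal (strict inequalities)
  at4 <- abnormal_areas(make_uniform_field(rep(4, 11)))
  expect_equal(at4$area_low_tawss, 0)
  at40 <- abnormal_areas(make_uniform_field(rep(40, 11)))
  expect_equal(at40$area_high_tawss, 0)

  # areas are monotone in their thresholds
  syn <- make_synthetic_wss_field(
    tibble::tibble(z_min = c(1, 5), z_max = c(3.5, 6.2),
                   mean = c(2, 60), amplitude = c(0, 0)),
    n_axial = 101, n_circumferential = 16, n_time = 20
  )
  a1 <- abnormal_areas(syn$field, high_tawss = 40)
  a2 <- abnormal_areas(syn$field, high_tawss = 70)
  expect_gte(a1$area_high_tawss, a2$area_high_tawss)
  expect_lte(a1$area_low_tawss + a1$area_high_tawss, a1$total_area)
})

test_that("the area quantifier recovers analytic band areas and refines with the mesh", {
  bands <- tibble::tibble(
    z_min = c(1, 4.5, 7), z_max = c(3.2, 5.5, 8.4),
    mean = c(2, 45, 5), amplitude = c(0, 0, 15)
  )
  syn <- make_synthetic_wss_field(bands, n_time = 20)
  got <- abnormal_areas(syn$field)
  truth <- syn$area_truth
  for (col in names(truth)) {
    expect_lt(abs(got[[col]] - truth[[col]]) / truth[[col]], 0.02)
  }
  fine <- make_synthetic_wss_field(bands, n_axial = 801,
                                   n_circumferential = 96, n_time = 20)
  got_fine <- abnormal_areas(fine$field)
  for (col in names(truth)) {
    expect_lt(abs(got_fine[[col]] - truth[[col]]) / truth[[col]], 0.01)
  }
})
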