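test_that("throat metrics reproduce every printed diameter and area cell", {
  ref <- printed_throat_table()
  for (i in seq_len(nrow(ref))) {
    tm <- throat_metrics(stenosis_spec(ref$vessel[i], ds = ref$ds[i]))
    expect_equal(round(tm$area, printed_decimals(ref$area[i])),
                 as.numeric(ref$area[i]),
                 info = sprintf("%s ds=%.1f area", ref$vessel[i], ref$ds[i]))
    expect_equal(round(tm$diameter, printed_decimals(ref$diameter[i])),
                 as.numeric(ref$diameter[i]),
                 info = sprintf("%s ds=%.1f diameter", ref$vessel[i], ref$ds[i]))
  }
})

test_that("throat area scales as the squared diameter ratio", {
  grid <- throat_table()
  normals <- throat_table(ds_levels = 0)
  for (v in unique(grid$vessel)) {
    a0 <- normals$area[normals$vessel == v]
    sub <- grid[grid$vessel == v, ]
    expect_equal(sub$area / a0, (1 - sub$ds)^2, tolerance = 1e-12)
  }
})

test_that("radius profile hits the throat exactly and is healthy outside the lesion", {
  spec <- stenosis_spec("LM", ds = 0.5)
  prof <- stenosed_radius_profile(spec, n_axial = 101)
  r0 <- 0.25
  expect_equal(min(prof$radius), r0 * 0.5, tolerance = 1e-9)
  lesion <- attr(prof, "lesion")
  outside <- prof$z < lesion[1] - 1e-12 | prof$z > lesion[2] + 1e-12
  expect_true(all(abs(prof$radius[outside] - r0) < 1e-12))
  expect_true(all(prof$center_offset == 0))

  # identity case: no stenosis leaves the healthy cylinder untouched
  flat <- stenosed_radius_profile(stenosis_spec("RCA", ds = 0))
  expect_true(all(flat$radius == 0.225))
  expect_true(all(flat$center_offset == 0))
})

test_that("eccentric profiles satisfy the wall-tangency condition", {
  spec <- stenosis_spec("LAD", ds = 0.3, eccentricity = "eccentric")
  prof <- stenosed_radius_profile(spec, n_axial = 151)
  r0 <- 0.22
  # offset + radius never exceeds the healthy wall, and equals it in the lesion
  expect_true(all(prof$center_offset + prof$radius <= r0 + 1e-9))
  expect_equal(max(prof$center_offset), (0.44 - 0.308) / 2, tolerance = 1e-9)
  throat <- which.min(prof$radius)
  expect_equal(prof$center_offset[throat] + prof$radius[throat], r0,
               tolerance = 1e-12)

  # eccentricity shifts the centre but not the cross-sectional area
  conc <- stenosed_radius_profile(stenosis_spec("LAD", 0.3), n_axial = 151)
  expect_equal(prof$radius, conc$radius, tolerance = 1e-14)
})

test_that("profile construction rejects invalid specifications", {
  expect_error(stenosis_spec("LM", ds = -0.1), "fraction")
  expect_error(stenosis_spec("LM", ds = 1.0), "fraction")
  expect_error(stenosis_spec("LM", ds = 0.8), "0.7")
  expect_error(stenosed_radius_profile(stenosis_spec("LM", 0.5), n_axial = 5),
               "at least 11")
  expect_error(vessel_spec("AORTA"), "must be one of")
})

test_that("surface mesh area matches the analytic value and converges at second order", {
  # straight cylinder
  cyl <- build_surface_mesh(
    stenosed_radius_profile(stenosis_spec("LM", 0), n_axial = 101), 48)
  expect_lt(abs(sum(cyl$patch_area) - 2 * pi * 0.25 * 1.0) / (2 * pi * 0.25),
            0.02)

  spec <- stenosis_spec("LM", ds = 0.5)
  a_exact <- analytic_revolution_area(spec)
  area_at <- function(na, nc) {
    sum(build_surface_mesh(stenosed_radius_profile(spec, na), nc)$patch_area)
  }
  e1 <- abs(area_at(101, 24) - a_exact)
  e2 <- abs(area_at(201, 48) - a_exact)
  expect_lt(abs(area_at(201, 48) - a_exact) / a_exact, 0.02)
  expect_gt(e1 / e2, 3)   # halving h cuts the error ~4x
  expect_lt(e1 / e2, 5.5)
})

test_that("throat ring and eccentric wall line are represented exactly in the mesh", {
  spec <- stenosis_spec("LM", ds = 0.5)
  mesh <- build_surface_mesh(stenosed_radius_profile(spec, 101), 64)
  ring_r <- sqrt(mesh$vertices[, 1]^2 + mesh$vertices[, 2]^2)
  # minimum ring circumference corresponds to the throat radius
  min_ring <- min(tapply(ring_r, mesh$ring, max))
  expect_equal(min_ring, 0.125, tolerance = 1e-9)

  ecc <- build_surface_mesh(
    stenosed_radius_profile(stenosis_spec("LM", 0.5, "eccentric"), 101), 32)
  # the theta = 0 vertex line stays on the healthy-wall cylinder
  line0 <- ecc$vertices[seq(1, nrow(ecc$vertices), by = 32), ]
  expect_true(all(abs(line0[, 1] - 0.25) < 1e-6))
  expect_true(all(abs(line0[, 2]) < 1e-12))
})

test_that("degenerate meshes are rejected", {
  prof <- stenosed_radius_profile(stenosis_spec("LM", 0.5), 41)
  bad <- prof
  bad$radius[3] <- 0
  expect_error(build_surface_mesh(bad), "positive")
  expect_error(build_surface_mesh(prof, n_circumferential = 6), "at least 12")
})
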