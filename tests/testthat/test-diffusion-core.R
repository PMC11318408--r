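test_that("zero consumption returns the boundary value exactly in both geometries", {
  sp <- slice_model_params(surface_po2 = 150, domain_depth = 160)
  f <- solve_planar_steady_state(sp, cmro2 = 0)
  expect_identical(unique(f$po2), 150)
  expect_length(f$po2, 161)

  kp <- krogh_params(capillary_po2 = 20, outer_radius = 25, cmro2 = 0)
  g <- solve_cylindrical_steady_state(kp)
  expect_identical(unique(g$po2), 20)
})

test_that("planar solver matches the zero-order closed form in the small-Km limit", {
  # p(L) = ps - M L^2 / (2D): 150 - 32*100^2/3200 = 50 mmHg
  sp <- slice_model_params(surface_po2 = 150, domain_depth = 100, km = 1e-3)
  f <- solve_planar_steady_state(sp, cmro2 = 32)
  expect_equal(f$po2[length(f$po2)], 50, tolerance = 0.2 / 50)

  # node-wise: parabolic profile, within 0.5% of the boundary value
  expected <- planar_zero_order(f$positions, 150, 32, 100)
  expect_lt(max(abs(f$po2 - expected)), 0.005 * 150)
})

test_that("cylindrical solver matches the Krogh-Erlang closed form in the small-Km limit", {
  kp <- krogh_params(capillary_po2 = 20, outer_radius = 25, cmro2 = 34.4,
                     capillary_radius = 3, km = 1e-3)
  f <- solve_cylindrical_steady_state(kp)
  edge <- f$po2[length(f$po2)]
  expected_edge <- krogh_erlang(25, 20, 34.4, 3, 25)  # ~9.065 mmHg
  expect_equal(edge, expected_edge, tolerance = 0.2 / expected_edge)
  # node-wise within 0.5% of the boundary value
  expected <- krogh_erlang(f$positions, 20, 34.4, 3, 25)
  expect_lt(max(abs(f$po2 - expected)), 0.005 * 20)
})

test_that("planar solver agrees node-wise with a fine-grid relaxation oracle", {
  # includes a configuration whose core is effectively anoxic
  cases <- list(list(ps = 150, L = 160, M = 34.4),
                list(ps = 400, L = 160, M = 92),
                list(ps = 150, L = 100, M = 34.4))
  for (cs in cases) {
    sp <- slice_model_params(surface_po2 = cs$ps, domain_depth = cs$L)
    f <- solve_planar_steady_state(sp, cmro2 = cs$M)
    oracle <- planar_fine_oracle(cs$ps, cs$L, cs$M)
    expect_lt(max(abs(f$po2 - oracle(f$positions))), 0.1)
  }
})

test_that("solvers agree node-wise with an independent shooting oracle", {
  skip_if_not_installed("deSolve")
  # planar, non-anoxic configuration
  sp <- slice_model_params(surface_po2 = 150, domain_depth = 100)
  f <- solve_planar_steady_state(sp, cmro2 = 34.4)
  sh <- planar_shoot_oracle(150, 100, 34.4, n_out = 101)
  ours <- stats::approx(f$positions, f$po2, xout = sh$depth)$y
  expect_lt(max(abs(ours - sh$po2)), 0.1)

  # cylindrical, Km = 3
  kp <- krogh_params(capillary_po2 = 20, outer_radius = 25, cmro2 = 34.4,
                     capillary_radius = 3)
  g <- solve_cylindrical_steady_state(kp)
  shc <- cyl_shoot_oracle(20, 3, 25, 34.4)
  ours <- stats::approx(g$positions, g$po2, xout = shc$radius)$y
  expect_lt(max(abs(ours - shc$po2)), 0.1)
})

test_that("halving the grid spacing changes no node by more than 0.1 mmHg", {
  sp1 <- slice_model_params(surface_po2 = 400, domain_depth = 160,
                            layer_thickness = 1)
  sp2 <- slice_model_params(surface_po2 = 400, domain_depth = 160,
                            layer_thickness = 0.5)
  f1 <- solve_planar_steady_state(sp1, 34.4)
  f2 <- solve_planar_steady_state(sp2, 34.4)
  on_coarse <- stats::approx(f2$positions, f2$po2, xout = f1$positions)$y
  expect_lt(max(abs(f1$po2 - on_coarse)), 0.1)

  kp1 <- krogh_params(capillary_po2 = 20, outer_radius = 27, cmro2 = 34.4,
                      shell_thickness = 1)
  kp2 <- krogh_params(capillary_po2 = 20, outer_radius = 27, cmro2 = 34.4,
                      shell_thickness = 0.5)
  g1 <- solve_cylindrical_steady_state(kp1)
  g2 <- solve_cylindrical_steady_state(kp2)
  on_coarse <- stats::approx(g2$positions, g2$po2, xout = g1$positions)$y
  expect_lt(max(abs(g1$po2 - on_coarse)), 0.1)
})

test_that("core/edge pO2 is monotone in consumption and in the boundary value", {
  cores <- vapply(seq(0, 100, by = 10), function(m) {
    f <- solve_planar_steady_state(
      slice_model_params(surface_po2 = 400, domain_depth = 160), m)
    f$po2[length(f$po2)]
  }, numeric(1))
  expect_true(all(diff(cores) < 0))

  surfaces <- vapply(seq(300, 500, by = 25), function(ps) {
    f <- solve_planar_steady_state(
      slice_model_params(surface_po2 = ps, domain_depth = 160), 34.4)
    f$po2[length(f$po2)]
  }, numeric(1))
  expect_true(all(diff(surfaces) > 0))

  edges <- vapply(seq(0, 92, by = 10), function(m) {
    minimal_ptio2(krogh_params(capillary_po2 = 40, outer_radius = 25,
                               cmro2 = m))
  }, numeric(1))
  expect_true(all(diff(edges) < 0))
})

test_that("cylindrical influx balances integrated shell consumption", {
  for (m in c(10, 34.4, 92)) {
    kp <- krogh_params(capillary_po2 = 30, outer_radius = 30, cmro2 = m)
    fb <- oxygen_flux_balance(solve_cylindrical_steady_state(kp), kp)
    expect_lt(fb$relative_error, 0.005)
  }
})

test_that("solution fields respect the oxygen-field invariants", {
  sp <- slice_model_params(surface_po2 = 400, domain_depth = 160)
  f <- solve_planar_steady_state(sp, 92)
  expect_true(all(f$po2 >= 0))
  expect_true(all(f$po2 <= f$boundary_value + 1e-9))
  expect_true(all(diff(f$po2) <= 1e-9))  # non-increasing from the source

  kp <- krogh_params(capillary_po2 = 20, outer_radius = 30, cmro2 = 92)
  g <- solve_cylindrical_steady_state(kp)
  expect_true(all(g$po2 >= 0))
  expect_true(all(diff(g$po2) <= 1e-9))
})

test_that("parameter constructors reject invalid physics", {
  expect_error(slice_model_params(surface_po2 = -1, domain_depth = 160),
               "surface_po2")
  expect_error(slice_model_params(surface_po2 = 150, domain_depth = 160,
                                  km = -3), "km")
  expect_error(slice_model_params(surface_po2 = 150, domain_depth = 160.5),
               "integer multiple")
  expect_error(krogh_params(capillary_po2 = 20, outer_radius = 2, cmro2 = 30,
                            capillary_radius = 3), "outer_radius")
  expect_error(krogh_params(capillary_po2 = 20, outer_radius = 25,
                            cmro2 = -1), "cmro2")
  sp <- slice_model_params(surface_po2 = 150, domain_depth = 160)
  expect_error(solve_planar_steady_state(sp, cmro2 = -5), "cmro2")
})

test_that("oxygen fields serialize to CSV and JSON", {
  f <- solve_planar_steady_state(
    slice_model_params(surface_po2 = 150, domain_depth = 100), 20)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_oxygen_field(f, csv)
  write_oxygen_field(f, json)
  d <- read.csv(csv)
  expect_equal(d$po2_mmHg, f$po2)
  j <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(j$po2_mmHg, f$po2)
  expect_equal(j$geometry, "planar")
  unlink(c(csv, json))
})
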