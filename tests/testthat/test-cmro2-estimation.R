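sp400 <- slice_model_params(surface_po2 = 400, domain_depth = 160)

sample_profile <- function(cmro2, depths, params = sp400, surface = TRUE) {
  f <- solve_planar_steady_state(params, cmro2)
  po2 <- stats::approx(f$positions, f$po2, xout = depths)$y
  depth_profile(depths, po2,
                surface_po2 = if (surface) params$surface_po2)
}

test_that("noiseless multi-step and three-point profiles round-trip exactly", {
  # multi-step every 20 um, anchored on the shallowest measurement
  prof <- sample_profile(40, seq(0, 160, by = 20), surface = FALSE)
  fit <- fit_cmro2(prof)
  expect_equal(fit$estimate, 40, tolerance = 1e-3)
  expect_lt(fit$sse, 1e-4)
  expect_true(fit$converged)

  # three-point design at the SD-level rate
  prof3 <- sample_profile(92, c(40, 100, 160))
  fit3 <- fit_cmro2(prof3)
  expect_equal(fit3$estimate, 92, tolerance = 1e-3)
  expect_equal(fit3$n_points, 3)
})

test_that("noisy-profile fit matches an exhaustive grid-search oracle", {
  prof <- generate_depth_profile(34.4, sp400, c(40, 100, 160), noise_sd = 1,
                                 seed = 77)
  fit <- fit_cmro2(prof, params = sp400)
  oracle <- grid_search_cmro2(prof, sp400)
  expect_lt(abs(fit$estimate - oracle), 0.011)
})

test_that("the SSE landscape is unimodal for noiseless forward profiles", {
  for (truth in c(34.4, 92)) {
    prof <- sample_profile(truth, c(40, 100, 160))
    sse <- vapply(seq(0, 500, by = 2.5), function(m) {
      f <- solve_planar_steady_state(sp400, m)
      pred <- stats::approx(f$positions, f$po2, xout = prof$depth)$y
      sum((pred - prof$po2)^2)
    }, numeric(1))
    imin <- which.min(sse)
    expect_true(all(diff(sse[seq_len(imin)]) <= 0))
    expect_true(all(diff(sse[imin:length(sse)]) >= 0))
  }
})

test_that("noisy three-point recovery has small bias and spread", {
  for (truth in c(34.4, 92)) {
    est <- vapply(1:200, function(i) {
      prof <- generate_depth_profile(truth, sp400, c(40, 100, 160),
                                     noise_sd = 1, seed = 1000 + i)
      fit_cmro2(prof, params = sp400)$estimate
    }, numeric(1))
    expect_lt(abs(stats::median(est) - truth) / truth, 0.02)
    expect_lt(sqrt(mean((est - truth)^2)) / truth, 0.08)
  }
})

test_that("fitted SD/baseline ratio reproduces the generating ratio", {
  f_base <- fit_cmro2(sample_profile(34.4, c(40, 100, 160)))
  f_sd <- fit_cmro2(sample_profile(92, c(40, 100, 160)))
  expect_equal(f_sd$estimate / f_base$estimate, 92 / 34.4, tolerance = 0.01 / 2.674)
})

test_that("fit validation catches malformed inputs and boundary hits", {
  expect_error(depth_profile(c(40, 100), c(100, 50)), "at least 3")
  expect_error(depth_profile(c(40, 30, 160), c(1, 2, 3)), "increasing")
  expect_error(depth_profile(c(40, 100, 160), c(1, -2, 3)), "non-negative")
  # domain mismatch
  prof <- sample_profile(40, c(40, 100, 160))
  sp_bad <- slice_model_params(surface_po2 = 400, domain_depth = 100)
  expect_error(fit_cmro2(prof, params = sp_bad), "core depth")
  # truth far above the search bound: boundary hit must be flagged
  prof_hi <- sample_profile(90, c(40, 100, 160))
  fit_hi <- fit_cmro2(prof_hi, m_max = 50)
  expect_false(fit_hi$converged)
  expect_identical(fit_hi$boundary_hit, "upper")
})

test_that("constant forward-model channels give a constant CMRO2 series", {
  f <- solve_planar_steady_state(sp400, 34.4)
  po2 <- stats::approx(f$positions, f$po2, xout = c(40, 100, 160))$y
  n <- 101
  tr <- trace_set(time = seq(0, 50, by = 0.5), dc = rep(0, n),
                  po2 = matrix(rep(po2, each = n), n), po2_depths = c(40, 100, 160),
                  k = rep(3, n))
  ser <- fit_cmro2_timeseries(tr, sp400, baseline_window = c(0, 10))
  expect_lt(max(abs(ser$estimates - 34.4)), 1e-2)
  expect_equal(ser$baseline, 34.4, tolerance = 1e-3)
})

test_that("time-resolved fits recover the generator peak-to-baseline ratio", {
  sc <- sd_scenario(sampling_rate = 2, duration = 300,
                    noise_sd = list(po2 = 0, dc = 0, k_voltage = 0))
  ep <- generate_sd_episode(sc, params = sp400, seed = 5)
  ser <- fit_cmro2_timeseries(ep, sp400, baseline_window = c(0, sc$onset))
  expect_equal(max(ser$estimates) / ser$baseline, 2.7, tolerance = 0.05 / 2.7)
})

test_that("series fitting rejects malformed traces", {
  expect_error(trace_set(time = numeric(0), dc = numeric(0),
                         po2 = matrix(numeric(0), 0, 3),
                         po2_depths = c(40, 100, 160), k = numeric(0)),
               "at least 2")
  expect_error(trace_set(time = c(0, 1, 3), dc = c(0, 0, 0),
                         po2 = matrix(1, 3, 3), po2_depths = c(40, 100, 160),
                         k = c(3, 3, 3)),
               "uniform")
  tr <- trace_set(time = 0:10, dc = rep(0, 11), po2 = matrix(50, 11, 2),
                  po2_depths = c(40, 100), k = rep(3, 11))
  expect_error(fit_cmro2_timeseries(tr, sp400), "at least 3")
})

test_that("excess-CMRO2 AUC integrates the series as expected", {
  mk_series <- function(est, t = seq(0, 400, by = 1), baseline = 10) {
    structure(list(times = t, estimates = est, baseline = baseline,
                   baseline_window = c(0, 30),
                   converged = rep(TRUE, length(t))),
              class = "cmro2_series")
  }
  t <- seq(0, 400, by = 1)
  # identically-baseline series -> 0
  expect_equal(excess_cmro2_auc(mk_series(rep(10, length(t))), onset = 50), 0)
  # 10 mmHg/s rectangle lasting 60 s -> 600 mmHg
  est <- rep(10, length(t)); est[t >= 100 & t < 160] <- 20
  expect_equal(excess_cmro2_auc(mk_series(est), onset = 50, horizon = 300), 600)
  # halving the excess halves the AUC (linearity)
  est_half <- 10 + (est - 10) / 2
  a1 <- excess_cmro2_auc(mk_series(est), onset = 50, horizon = 300)
  a2 <- excess_cmro2_auc(mk_series(est_half), onset = 50, horizon = 300)
  expect_equal(a2 / a1, 0.5, tolerance = 0.01)
  # negative excess is clipped, not subtracted
  est_dip <- rep(10, length(t)); est_dip[t >= 100 & t < 160] <- 5
  expect_equal(excess_cmro2_auc(mk_series(est_dip), onset = 50), 0)
  # horizon beyond the series end names the shortfall
  expect_error(excess_cmro2_auc(mk_series(rep(10, length(t))), onset = 200,
                                horizon = 300), "short")
})

test_that("generator episodes halve their AUC when the excess is halved", {
  mk <- function(ratio) {
    sc <- sd_scenario(peak_ratio = ratio, sampling_rate = 2, duration = 400,
                      noise_sd = list(po2 = 0, dc = 0, k_voltage = 0))
    ep <- generate_sd_episode(sc, params = sp400, seed = 11)
    ser <- fit_cmro2_timeseries(ep, sp400, baseline_window = c(0, sc$onset))
    excess_cmro2_auc(ser, onset = sc$onset, horizon = 300)
  }
  full <- mk(2.7)
  half <- mk(1 + 1.7 / 2)
  expect_equal(half / full, 0.5, tolerance = 0.01)
})
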