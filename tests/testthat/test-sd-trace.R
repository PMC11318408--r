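test_that("Nernst conversion maps baseline and decade steps correctly", {
  cal <- nernst_calibration()
  expect_equal(cal$slope, log(10) * 8.314462618 * 309.15 / 96485.33212 * 1000)
  expect_equal(voltage_to_potassium(c(0, 0, 0), cal, baseline_mv = 0),
               c(3, 3, 3))
  # one decade of voltage is a tenfold concentration change
  expect_equal(voltage_to_potassium(cal$slope, cal, baseline_mv = 0), 30)
  expect_error(voltage_to_potassium(numeric(0), cal), "empty")
})

test_that("voltage -> mM -> voltage round trip is exact to well below 1 nV", {
  cal <- nernst_calibration(slope = 58)  # calibrated, non-ideal electrode
  v <- c(-2, 0, 5, 20, 61.3, 80)
  k <- voltage_to_potassium(v, cal, baseline_mv = 0)
  expect_lt(max(abs(potassium_to_voltage(k, cal) - v)), 1e-9)
})

test_that("SD onset detection finds generator onsets and ignores quiet traces", {
  # flat noise-free trace: no SD, not an error
  t <- seq(0, 120, by = 0.1)
  expect_true(is.na(detect_sd_onset(t, rep(-3, length(t)))))

  # synthetic episode: onset within 1 s of the generator's
  sc <- sd_scenario(sampling_rate = 10, duration = 200,
                    noise_sd = list(po2 = 0, dc = 0, k_voltage = 0))
  ep <- generate_sd_episode(sc, seed = 3)
  expect_lt(abs(detect_sd_onset(ep$time, ep$dc) - sc$onset), 1)

  # trace starting mid-event: baseline window missing
  expect_error(detect_sd_onset(t, rep(0, length(t)),
                               baseline_window = c(-60, -30)),
               "baseline window")
})

test_that("feature extraction round-trips the generator landmarks", {
  sc <- sd_scenario(noise_sd = list(po2 = 0, dc = 0, k_voltage = 0))
  ep <- generate_sd_episode(sc, seed = 7)
  ft <- extract_sd_features(ep)
  dt <- 1 / sc$sampling_rate
  expect_true(ft$detected)
  expect_equal(ft$delta_k, sc$delta_k, tolerance = 0.02)
  expect_lt(abs(ft$t1_50 - sc$t1_50), dt)
  expect_lt(abs(ft$t2_50 - sc$t2_50), dt)
  expect_lt(abs(ft$dc_duration - sc$dc_duration), dt)
  expect_equal(ft$dc_amplitude, sc$dc_amplitude, tolerance = 0.02)
  expect_false(ft$t2_50_censored)
  expect_true(ft$t1_50 <= ft$t2_50)
})

test_that("hypoxia is flagged from the core-channel minimum", {
  mk_trace <- function(core_min) {
    t <- seq(0, 200, by = 0.5)
    n <- length(t)
    dc <- rep(0, n); dc[t >= 60 & t <= 100] <- -12
    dip <- 30 - (30 - core_min) * exp(-((t - 80) / 15)^2)
    po2 <- cbind(rep(120, n), rep(60, n), dip)
    trace_set(t, dc, po2, c(40, 100, 160), k = rep(3, n))
  }
  expect_true(extract_sd_features(mk_trace(7.5))$hypoxia)
  expect_false(extract_sd_features(mk_trace(8.5))$hypoxia)
})

test_that("features are invariant to DC offset and time shift", {
  sc <- sd_scenario(sampling_rate = 5, duration = 200,
                    noise_sd = list(po2 = 0, dc = 0, k_voltage = 0))
  ep <- generate_sd_episode(sc, seed = 9)
  ft <- extract_sd_features(ep)

  ep_off <- ep
  ep_off$dc <- ep$dc + 37.5
  ft_off <- extract_sd_features(ep_off)
  expect_equal(ft_off$dc_amplitude, ft$dc_amplitude)
  expect_equal(ft_off$dc_duration, ft$dc_duration)
  expect_equal(ft_off$onset, ft$onset)

  ep_shift <- ep
  ep_shift$time <- ep$time + 500
  ft_shift <- extract_sd_features(ep_shift)
  expect_equal(ft_shift$onset, ft$onset + 500)
  expect_equal(ft_shift$delta_k, ft$delta_k)
  expect_equal(ft_shift$t1_50, ft$t1_50)
})

test_that("a trace without an SD reports 'not detected' rather than features", {
  t <- seq(0, 120, by = 0.2)
  n <- length(t)
  tr <- trace_set(t, rep(0, n), matrix(c(120, 60, 30), n, 3, byrow = TRUE),
                  c(40, 100, 160), k = rep(3, n))
  ft <- extract_sd_features(tr)
  expect_false(ft$detected)
  expect_identical(as.data.frame(ft), data.frame(detected = FALSE))
})

test_that("an unrecovered potassium transient is censored, not fabricated", {
  # decay so slow the trace ends before 10% recovery
  sc <- sd_scenario(t1_50 = 60, t2_50 = 400, duration = 220,
                    noise_sd = list(po2 = 0, dc = 0, k_voltage = 0))
  ep <- generate_sd_episode(sc, seed = 13)
  ft <- extract_sd_features(ep)
  expect_true(ft$t2_50_censored)
  expect_true(is.na(ft$t2_50))
  expect_false(is.na(ft$t1_50))
})

test_that("isoflurane conversion reproduces the standard aqueous values", {
  expect_identical(isoflurane_percent_to_mM(1), 0.24)
  expect_identical(isoflurane_percent_to_mM(3), 0.72)
  expect_identical(isoflurane_percent_to_mM(0), 0)
  expect_error(isoflurane_percent_to_mM(-1), "non-negative")
  # strictly proportional at full precision
  full <- isoflurane_percent_to_mM(c(1, 2, 4), digits = NULL)
  expect_equal(full / full[1], c(1, 2, 4))
})

test_that("trace sets round-trip through CSV with either potassium encoding", {
  sc <- sd_scenario(sampling_rate = 2, duration = 150)
  ep <- generate_sd_episode(sc, seed = 21)
  path <- tempfile(fileext = ".csv")
  write_trace_set(ep, path)
  back <- read_trace_set(path)
  expect_equal(back$time, ep$time)
  expect_equal(back$k_voltage, ep$k_voltage)
  expect_equal(unname(back$po2), unname(ep$po2))
  expect_equal(back$po2_depths, ep$po2_depths)
  unlink(path)
})
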