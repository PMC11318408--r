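sp400 <- slice_model_params(surface_po2 = 400, domain_depth = 160)

test_that("noiseless depth profiles equal the forward solution exactly", {
  f <- solve_planar_steady_state(sp400, 34.4)
  prof <- generate_depth_profile(34.4, sp400, c(40, 100, 160), noise_sd = 0)
  expect_equal(prof$po2, f$po2[c(41, 101, 161)])
  gt <- attr(prof, "ground_truth")
  expect_equal(gt$cmro2, 34.4)
})

test_that("profile noise has the configured magnitude", {
  f <- solve_planar_steady_state(sp400, 34.4)
  truth <- f$po2[c(41, 101, 161)]
  res <- vapply(1:1000, function(i) {
    p <- generate_depth_profile(34.4, sp400, c(40, 100, 160), noise_sd = 1,
                                seed = 5000 + i)
    p$po2 - truth
  }, numeric(3))
  expect_equal(stats::sd(as.vector(res)), 1, tolerance = 0.1)
})

test_that("generators are pure functions of parameters and seed", {
  p1 <- generate_depth_profile(40, sp400, c(40, 100, 160), noise_sd = 1,
                               seed = 42)
  p2 <- generate_depth_profile(40, sp400, c(40, 100, 160), noise_sd = 1,
                               seed = 42)
  p3 <- generate_depth_profile(40, sp400, c(40, 100, 160), noise_sd = 1,
                               seed = 43)
  expect_identical(p1$po2, p2$po2)
  expect_false(identical(p1$po2, p3$po2))

  sc <- sd_scenario(sampling_rate = 2, duration = 120, onset = 50)
  e1 <- generate_sd_episode(sc, params = sp400, seed = 8)
  e2 <- generate_sd_episode(sc, params = sp400, seed = 8)
  expect_identical(e1$dc, e2$dc)
  expect_identical(e1$k_voltage, e2$k_voltage)
  expect_identical(e1$po2, e2$po2)

  # generation does not disturb the global RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(generate_sd_episode(sc, params = sp400, seed = 8))
  expect_identical(stats::runif(1), before)
})

test_that("out-of-domain depths are rejected", {
  expect_error(generate_depth_profile(40, sp400, c(40, 100, 200)),
               "within")
})

test_that("the two-landmark decay passes exactly through both landmarks", {
  for (lm in list(c(20, 65), c(38.3, 235.7), c(5, 10))) {
    d <- solve_decay_landmarks(lm[1], lm[2])
    expect_equal(d$decay(lm[1]), 0.5, tolerance = 1e-12)
    expect_equal(d$decay(lm[2]), 0.1, tolerance = 1e-12)
    expect_equal(d$decay(0), 1)
  }
  expect_error(solve_decay_landmarks(30, 20), "t1_50 < t2_50")
  expect_error(solve_decay_landmarks(-1, 20), "t1_50 < t2_50")
})

test_that("noiseless episode channels respect the forward model exactly", {
  sc <- sd_scenario(sampling_rate = 2, duration = 120, onset = 50,
                    noise_sd = list(po2 = 0, dc = 0, k_voltage = 0))
  ep <- generate_sd_episode(sc, params = sp400, seed = 1)
  # pre-onset samples are the baseline steady state
  f <- solve_planar_steady_state(sp400, sc$baseline_cmro2)
  expect_equal(unname(ep$po2[1, ]), f$po2[c(41, 101, 161)], tolerance = 1e-9)
  # the generating waveform peaks at peak_ratio x baseline (up to the
  # sampling of the kernel maximum)
  gt <- attr(ep, "ground_truth")
  expect_equal(max(gt$cmro2_t) / sc$baseline_cmro2, sc$peak_ratio,
               tolerance = 1e-4)
})

test_that("paired cohorts have the requested paired structure", {
  scc <- sd_scenario()
  sct <- sd_scenario(delta_k = 16.5, t1_50 = 38.3, t2_50 = 235.7,
                     dc_duration = 107)
  coh <- generate_paired_cohort(scc, sct, n_slices = 13, seed = 4)
  expect_equal(nrow(coh), 26)
  expect_equal(sum(coh$condition == "control"), 13)
  expect_equal(sort(unique(coh$slice)), 1:13)
  # same seed reproduces, different seed does not
  coh2 <- generate_paired_cohort(scc, sct, n_slices = 13, seed = 4)
  expect_identical(coh$delta_k, coh2$delta_k)
  expect_error(generate_paired_cohort(scc, sct, n_slices = 0), "n_slices")
})

test_that("zero-effect cohorts reject at close to the nominal level", {
  sc <- sd_scenario()
  reject <- vapply(1:500, function(i) {
    coh <- generate_paired_cohort(sc, sc, n_slices = 13, seed = 20000 + i)
    d <- coh$delta_k[coh$condition == "treated"] -
      coh$delta_k[coh$condition == "control"]
    wilcoxon_signed_rank(d)$p_value < 0.05
  }, logical(1))
  # alpha +/- 2 SE at 500 replicates, discrete exact test included
  expect_gt(mean(reject), 0.05 - 2 * sqrt(0.05 * 0.95 / 500) - 0.01)
  expect_lt(mean(reject), 0.05 + 2 * sqrt(0.05 * 0.95 / 500) + 0.01)
})

test_that("the reported treatment effect is detectable and stable across seeds", {
  scc <- sd_scenario()
  sct <- sd_scenario(delta_k = 16.5)
  rate <- function(seeds) {
    mean(vapply(seeds, function(s) {
      coh <- generate_paired_cohort(scc, sct, n_slices = 13, seed = s)
      d <- coh$delta_k[coh$condition == "treated"] -
        coh$delta_k[coh$condition == "control"]
      wilcoxon_signed_rank(d)$p_value < 0.05
    }, logical(1)))
  }
  r1 <- rate(30001:30300)
  r2 <- rate(60001:60300)
  expect_gt(r1, 0.2)          # the shifted transient is detectable at n = 13
  expect_lt(abs(r1 - r2), 0.12)  # and its power estimate is seed-stable
})

test_that("episode-mode cohorts run features through the full extractor", {
  scc <- sd_scenario(sampling_rate = 2, duration = 150, onset = 40,
                     noise_sd = list(po2 = 0.5, dc = 0.1, k_voltage = 0.1))
  coh <- generate_paired_cohort(scc, scc, n_slices = 1, seed = 2,
                                mode = "episodes")
  expect_equal(nrow(coh), 2)
  expect_true(all(is.finite(coh$delta_k)))
  gt <- attr(coh, "ground_truth")
  # recovered transients track the slice multiplier within measurement error
  expected <- scc$delta_k * gt$slice_multiplier_delta_k
  expect_equal(coh$delta_k, rep(expected, 2), tolerance = 0.05)
})
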