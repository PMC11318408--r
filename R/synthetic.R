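#' Scenario parameters for a synthetic SD episode
#'
#' Defines the landmark statistics of a generated spreading-depolarization
#' episode. Defaults are the study-condition medians of the untreated (aCSF)
#' condition: baseline CMRO2 34.4 mmHg/s rising ~2.7-fold at the SD peak, a
#' negative DC shift of 43 s half-amplitude width, a potassium transient of
#' +22.6 mM decaying to 50%/10% of its peak rise in 20 s / 65 s. The DC
#' amplitude default (15 mV) is a plausible placeholder only - it is a
#' configuration value, not a study statistic.
#'
#' @param baseline_cmro2 Pre-SD CMRO2, mmHg/s.
#' @param peak_ratio Peak CMRO2 over baseline (>= 1).
#' @param cmro2_rise_tau,cmro2_decay_tau Rise and decay time constants of the
#'   CMRO2 waveform, s. The defaults (10 s rise, 120 s decay) make elevated
#'   consumption outlast DC recovery, as observed in the recordings the
#'   generator emulates.
#' @param dc_amplitude Negative DC shift amplitude, mV (placeholder default).
#' @param dc_duration Half-amplitude width of the DC shift, s.
#' @param dc_edge_tau Logistic edge time constant of the DC shift, s.
#' @param delta_k Peak potassium rise above baseline, mM.
#' @param t1_50,t2_50 Times from the potassium peak to 50% and 10% of the
#'   rise, s (`t1_50 < t2_50`).
#' @param k_rise_s Linear rise time of the potassium transient, s.
#' @param onset Event onset, s.
#' @param duration Total trace duration, s.
#' @param sampling_rate Hz.
#' @param noise_sd Named list of channel noise SDs: `po2` (mmHg), `dc` (mV),
#'   `k_voltage` (mV).
#' @return An `sd_scenario` object.
#' @export
sd_scenario <- function(baseline_cmro2 = 34.4, peak_ratio = 2.7,
                        cmro2_rise_tau = 10, cmro2_decay_tau = 120,
                        dc_amplitude = 15, dc_duration = 43,
                        dc_edge_tau = 0.5, delta_k = 22.6, t1_50 = 20,
                        t2_50 = 65, k_rise_s = 10, onset = 60,
                        duration = 420, sampling_rate = 10,
                        noise_sd = list(po2 = 1, dc = 0.2, k_voltage = 0.2)) {
  for (nm in c("baseline_cmro2", "cmro2_rise_tau", "cmro2_decay_tau",
               "dc_amplitude", "dc_duration", "dc_edge_tau", "delta_k",
               "t1_50", "t2_50", "k_rise_s", "onset", "duration",
               "sampling_rate")) {
    check_positive_scalar(get(nm), nm)
  }
  if (peak_ratio < 1) stop("`peak_ratio` must be >= 1", call. = FALSE)
  if (t1_50 >= t2_50) stop("`t1_50` must be smaller than `t2_50`",
                           call. = FALSE)
  noise <- utils::modifyList(list(po2 = 1, dc = 0.2, k_voltage = 0.2),
                             as.list(noise_sd))
  if (any(unlist(noise) < 0)) stop("noise SDs must be non-negative",
                                   call. = FALSE)
  structure(list(baseline_cmro2 = baseline_cmro2, peak_ratio = peak_ratio,
                 cmro2_rise_tau = cmro2_rise_tau,
                 cmro2_decay_tau = cmro2_decay_tau,
                 dc_amplitude = dc_amplitude, dc_duration = dc_duration,
                 dc_edge_tau = dc_edge_tau, delta_k = delta_k,
                 t1_50 = t1_50, t2_50 = t2_50, k_rise_s = k_rise_s,
                 onset = onset, duration = duration,
                 sampling_rate = sampling_rate, noise_sd = noise),
            class = "sd_scenario")
}

# run an expression with a locally seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a (possibly noisy) oxygen depth profile from the forward model
#'
#' Samples the planar steady-state solution at the requested depths and adds
#' i.i.d. Gaussian measurement noise (clamped at 0 mmHg, the physical floor
#' of a Clark electrode reading). Ground truth travels with the profile.
#'
#' @param cmro2 True CMRO2, mmHg/s.
#' @param params A [slice_model_params()].
#' @param depths Measurement depths, um, within `[0, domain_depth]`.
#' @param noise_sd Gaussian noise SD, mmHg.
#' @param seed Optional integer seed (local to this call).
#' @return A [depth_profile()] with attribute `ground_truth` (a list with the
#'   generating `cmro2`, `noise_sd` and `seed`).
#' @examples
#' sp <- slice_model_params(surface_po2 = 400, domain_depth = 160)
#' generate_depth_profile(34.4, sp, depths = c(40, 100, 160))
#' @export
generate_depth_profile <- function(cmro2, params, depths, noise_sd = 0,
                                   seed = NULL) {
  stopifnot(inherits(params, "slice_model_params"))
  if (any(depths < 0 | depths > params$domain_depth)) {
    stop("`depths` must lie within [0, ", params$domain_depth, "] um",
         call. = FALSE)
  }
  f <- solve_planar_steady_state(params, cmro2)
  po2 <- stats::approx(f$positions, f$po2, xout = depths)$y
  if (noise_sd > 0) {
    po2 <- with_seed(seed, po2 + stats::rnorm(length(po2), sd = noise_sd))
  }
  prof <- depth_profile(depths, pmax(po2, 0),
                        surface_po2 = params$surface_po2)
  attr(prof, "ground_truth") <- list(cmro2 = cmro2, noise_sd = noise_sd,
                                     seed = seed)
  prof
}

#' Solve a two-landmark decay law for the potassium transient
#'
#' Finds the stretched-exponential (Weibull) decay
#' `exp(-(t / tau)^beta)` that passes exactly through 50% of the initial
#' value at `t1_50` and 10% at `t2_50`. The closed form
#' `beta = log(log(0.1)/log(0.5)) / log(t2_50/t1_50)`,
#' `tau = t1_50 / (-log(0.5))^(1/beta)` exists for any `0 < t1_50 < t2_50`:
#' `beta = 1` recovers a plain exponential, `beta < 1` a heavy (slower than
#' exponential) tail, `beta > 1` a compressed tail. A positive mixture of two
#' exponentials cannot represent compressed tails at all (mixtures are
#' log-convex, so the plain exponential already minimizes the 10%-landmark
#' time given the 50% one), which is why this family is used instead.
#'
#' @param t1_50,t2_50 Times to 50% and 10% of the initial value, s.
#' @return List with `tau`, `beta` and the decay function `decay(t)`
#'   (`decay(0) = 1`).
#' @examples
#' d <- solve_decay_landmarks(20, 65)
#' d$decay(c(20, 65))  # 0.5, 0.1
#' @export
solve_decay_landmarks <- function(t1_50, t2_50) {
  if (!is.numeric(t1_50) || !is.numeric(t2_50) || t1_50 <= 0 ||
      t2_50 <= t1_50) {
    stop("decay landmarks need 0 < t1_50 < t2_50 (got ", t1_50, ", ", t2_50,
         ")", call. = FALSE)
  }
  beta <- log(log(0.1) / log(0.5)) / log(t2_50 / t1_50)
  tau <- t1_50 / (-log(0.5))^(1 / beta)
  list(tau = tau, beta = beta,
       decay = function(t) exp(-(pmax(t, 0) / tau)^beta))
}

# normalized CMRO2 excess kernel: saturating rise times exponential decay,
# peak scaled to exactly 1
cmro2_kernel <- function(t, onset, rise_tau, decay_tau) {
  u <- pmax(t - onset, 0)
  raw <- (1 - exp(-u / rise_tau)) * exp(-u / decay_tau)
  u_peak <- rise_tau * log((rise_tau + decay_tau) / rise_tau)
  peak <- (1 - exp(-u_peak / rise_tau)) * exp(-u_peak / decay_tau)
  ifelse(t > onset, raw / peak, 0)
}

#' Generate a complete synthetic SD episode with ground truth
#'
#' Builds a [trace_set()] whose channels follow the scenario's landmark
#' statistics exactly (in the noiseless limit):
#' * `CMRO2(t)`: baseline plus an excess kernel (saturating rise, exponential
#'   decay) peaking at `peak_ratio * baseline`;
#' * `DC(t)`: a logistic-edged negative rectangle with the configured
#'   amplitude and half-amplitude width `dc_duration`;
#' * potassium: linear rise to `baseline + delta_k` over `k_rise_s`, then the
#'   stretched-exponential decay of [solve_decay_landmarks()] hitting the
#'   50%/10% landmarks at `t1_50`/`t2_50`; emitted as electrode voltage
#'   through the inverse Nernst map;
#' * pO2 channels: quasi-steady planar forward solutions under `CMRO2(t)`,
#'   sampled at the electrode depths.
#'
#' Gaussian noise (per-channel SDs from the scenario) is added last; the
#' generator is a pure function of (parameters, seed) and never leaks ground
#' truth into the channels.
#'
#' @param scenario An [sd_scenario()].
#' @param params A [slice_model_params()]; default surface pO2 400 mmHg and
#'   core depth 160 um (interface-chamber supply over a 40/100/160-um
#'   electrode array).
#' @param depths pO2 electrode depths, um; the deepest is the core.
#' @param calib A [nernst_calibration()] for the emitted potassium voltage.
#' @param seed Optional integer seed (local to this call).
#' @return A `trace_set` with attribute `ground_truth`: the scenario, the
#'   model parameters, and the generating `cmro2_t` waveform.
#' @export
generate_sd_episode <- function(scenario = sd_scenario(),
                                params = slice_model_params(
                                  surface_po2 = 400, domain_depth = 160),
                                depths = c(40, 100, 160),
                                calib = nernst_calibration(), seed = NULL) {
  stopifnot(inherits(scenario, "sd_scenario"),
            inherits(params, "slice_model_params"))
  if (max(depths) != params$domain_depth) {
    stop("the deepest electrode (", max(depths),
         " um) must sit at the model core depth (", params$domain_depth,
         " um)", call. = FALSE)
  }
  sc <- scenario
  time <- seq(0, sc$duration, by = 1 / sc$sampling_rate)
  n <- length(time)

  # CMRO2 waveform
  kernel <- cmro2_kernel(time, sc$onset, sc$cmro2_rise_tau, sc$cmro2_decay_tau)
  cmro2_t <- sc$baseline_cmro2 * (1 + (sc$peak_ratio - 1) * kernel)

  # DC: logistic-edged negative rectangle, half-amplitude width dc_duration
  edge <- function(t, a, sgn) 1 / (1 + exp(-sgn * (t - a) / sc$dc_edge_tau))
  shape <- edge(time, sc$onset, 1) * edge(time, sc$onset + sc$dc_duration, -1)
  dc <- -sc$dc_amplitude * shape / max(shape)

  # potassium: linear rise then stretched-exponential decay through the
  # landmarks
  dec <- solve_decay_landmarks(sc$t1_50, sc$t2_50)
  t_peak <- sc$onset + sc$k_rise_s
  rise <- pmin(pmax((time - sc$onset) / sc$k_rise_s, 0), 1)
  fall <- ifelse(time > t_peak, dec$decay(time - t_peak), 1)
  k <- calib$baseline_k + sc$delta_k * rise * fall
  k_voltage <- potassium_to_voltage(k, calib)

  # quasi-steady pO2 channels (interpolation weights precomputed once)
  h <- params$layer_thickness
  lo <- pmin(floor(depths / h), params$n_layers - 1L)
  frac <- depths / h - lo
  po2 <- matrix(NA_real_, n, length(depths))
  for (i in seq_len(n)) {
    p <- .planar_solve_cpp(params$surface_po2, params$n_layers, h,
                           params$diffusion_constant, params$km, cmro2_t[i],
                           1e-6, 10000L)
    po2[i, ] <- p[lo + 1L] * (1 - frac) + p[lo + 2L] * frac
  }

  traces <- with_seed(seed, {
    dc_n <- dc + stats::rnorm(n, sd = sc$noise_sd$dc)
    kv_n <- k_voltage + stats::rnorm(n, sd = sc$noise_sd$k_voltage)
    po2_n <- pmax(po2 + stats::rnorm(n * ncol(po2), sd = sc$noise_sd$po2), 0)
    trace_set(time = time, dc = dc_n, po2 = po2_n, po2_depths = depths,
              k_voltage = kv_n)
  })
  attr(traces, "ground_truth") <- list(
    scenario = sc, params = params, depths = depths, seed = seed,
    cmro2_t = cmro2_t, decay_tau = dec$tau, decay_beta = dec$beta,
    k_peak_time = t_peak)
  traces
}

#' Generate a paired (repeated-measures) synthetic cohort
#'
#' Emulates the within-slice design in which every slice is recorded once
#' under a control condition and once under a treated condition. Slice-level
#' variability enters as lognormal multipliers on baseline CMRO2 and on the
#' potassium transient, shared between the two conditions of a slice;
#' episode-level (measurement) variability enters as independent lognormal
#' noise on every feature. Under a zero treatment effect the paired
#' differences are therefore symmetric about zero.
#'
#' With `mode = "features"` the per-episode feature values are drawn directly
#' from the generating parameters (fast; suitable for operating-characteristic
#' simulations). With `mode = "episodes"` full trace sets are generated per
#' episode and features recovered with [extract_sd_features()] (slow; one
#' full round trip through the pipeline).
#'
#' @param scenario_control,scenario_treated [sd_scenario()] objects for the
#'   two conditions.
#' @param n_slices Number of slices (>= 1).
#' @param seed Optional integer seed (local to this call).
#' @param slice_sdlog Named list, lognormal SDs of the slice-level
#'   multipliers: `cmro2` (default 0.2) and `delta_k` (default 0.5), chosen
#'   to match the dispersion implied by reported interquartile ranges.
#' @param episode_sdlog Lognormal SD of the episode-level measurement noise
#'   applied to every feature.
#' @param mode `"features"` or `"episodes"` (see above).
#' @param ... Further arguments passed to [generate_sd_episode()] in
#'   `"episodes"` mode.
#' @return A data frame with one row per slice x condition and columns
#'   `slice`, `condition`, `baseline_cmro2`, `sd_cmro2`, `delta_k`,
#'   `dc_duration`, `t1_50`, `t2_50`; attribute `ground_truth` records the
#'   scenarios, multipliers and seed.
#' @export
generate_paired_cohort <- function(scenario_control, scenario_treated,
                                   n_slices, seed = NULL,
                                   slice_sdlog = list(cmro2 = 0.2,
                                                      delta_k = 0.5),
                                   episode_sdlog = 0.15,
                                   mode = c("features", "episodes"), ...) {
  stopifnot(inherits(scenario_control, "sd_scenario"),
            inherits(scenario_treated, "sd_scenario"))
  mode <- match.arg(mode)
  if (!is.numeric(n_slices) || n_slices < 1) {
    stop("`n_slices` must be >= 1", call. = FALSE)
  }
  n_slices <- as.integer(n_slices)
  sdl <- utils::modifyList(list(cmro2 = 0.2, delta_k = 0.5),
                           as.list(slice_sdlog))

  with_seed(seed, {
    m_cmro2 <- stats::rlnorm(n_slices, 0, sdl$cmro2)
    m_k <- stats::rlnorm(n_slices, 0, sdl$delta_k)
    scen <- list(control = scenario_control, treated = scenario_treated)

    if (mode == "features") {
      n2 <- 2L * n_slices
      slice <- rep(seq_len(n_slices), each = 2L)
      condition <- rep(c("control", "treated"), times = n_slices)
      sc_of <- function(field) {
        vapply(scen, `[[`, numeric(1), field)[condition]
      }
      e <- function() stats::rlnorm(n2, 0, episode_sdlog)
      out <- data.frame(
        slice = slice, condition = condition,
        baseline_cmro2 = sc_of("baseline_cmro2") * m_cmro2[slice] * e(),
        sd_cmro2 = sc_of("baseline_cmro2") * sc_of("peak_ratio") *
          m_cmro2[slice] * e(),
        delta_k = sc_of("delta_k") * m_k[slice] * e(),
        dc_duration = sc_of("dc_duration") * e(),
        t1_50 = sc_of("t1_50") * e(), t2_50 = sc_of("t2_50") * e())
    } else {
      rows <- vector("list", 2L * n_slices)
      idx <- 0L
      for (s in seq_len(n_slices)) {
        for (cond in c("control", "treated")) {
          sc <- scen[[cond]]
          idx <- idx + 1L
          sc_i <- sd_scenario(
            baseline_cmro2 = sc$baseline_cmro2 * m_cmro2[s],
            peak_ratio = sc$peak_ratio,
            cmro2_rise_tau = sc$cmro2_rise_tau,
            cmro2_decay_tau = sc$cmro2_decay_tau,
            dc_amplitude = sc$dc_amplitude, dc_duration = sc$dc_duration,
            dc_edge_tau = sc$dc_edge_tau,
            delta_k = sc$delta_k * m_k[s], t1_50 = sc$t1_50,
            t2_50 = sc$t2_50, k_rise_s = sc$k_rise_s, onset = sc$onset,
            duration = sc$duration, sampling_rate = sc$sampling_rate,
            noise_sd = sc$noise_sd)
          ep_seed <- as.integer(stats::runif(1, 1, 2^30))
          ep <- generate_sd_episode(sc_i, seed = ep_seed, ...)
          ft <- extract_sd_features(ep)
          rows[[idx]] <- data.frame(
            slice = s, condition = cond,
            baseline_cmro2 = NA_real_, sd_cmro2 = NA_real_,
            delta_k = ft$delta_k, dc_duration = ft$dc_duration,
            t1_50 = ft$t1_50, t2_50 = ft$t2_50)
        }
      }
      out <- do.call(rbind, rows)
    }
    attr(out, "ground_truth") <- list(
      scenario_control = scenario_control,
      scenario_treated = scenario_treated,
      slice_multiplier_cmro2 = m_cmro2, slice_multiplier_delta_k = m_k,
      slice_sdlog = sdl, episode_sdlog = episode_sdlog, seed = seed,
      mode = mode)
    out
  })
}
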