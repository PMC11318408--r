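#' Construct an oxygen depth profile
#'
#' A depth profile is the set of (depth, pO2) measurements taken from the
#' slice surface toward the ptiO2 minimum ("core"), acquired either by a
#' single electrode stepped vertically (multi-step design, typically every
#' 20 um) or by three electrodes at fixed depths (three-point design, e.g.
#' 40/100/160 um).
#'
#' @param depth Depths in um, strictly increasing, first >= 0. The last depth
#'   defines the core (closed-boundary) depth.
#' @param po2 Measured pO2 in mmHg, same length as `depth`, all >= 0.
#' @param surface_po2 Optional supply pO2 at the slice surface, mmHg. Required
#'   later for three-point fits; multi-step fits can instead anchor on the
#'   shallowest measurement.
#' @return A `depth_profile` object.
#' @examples
#' depth_profile(c(40, 100, 160), c(120, 85, 60), surface_po2 = 150)
#' @export
depth_profile <- function(depth, po2, surface_po2 = NULL) {
  if (!is.numeric(depth) || !is.numeric(po2) || length(depth) != length(po2)) {
    stop("`depth` and `po2` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (length(depth) < 3L) {
    stop("a depth profile needs at least 3 records (the three-point design ",
         "is the minimum)", call. = FALSE)
  }
  if (anyNA(depth) || anyNA(po2)) stop("missing values in profile", call. = FALSE)
  if (depth[1] < 0 || any(diff(depth) <= 0)) {
    stop("depths must be strictly increasing and non-negative", call. = FALSE)
  }
  if (any(po2 < 0)) stop("pO2 values must be non-negative", call. = FALSE)
  if (!is.null(surface_po2)) check_positive_scalar(surface_po2, "surface_po2")
  structure(list(depth = depth, po2 = po2, surface_po2 = surface_po2,
                 core_depth = depth[length(depth)]),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("Depth profile: ", length(x$depth), " points, core at ", x$core_depth,
      " um", if (!is.null(x$surface_po2))
        paste0(", surface pO2 ", x$surface_po2, " mmHg"), "\n", sep = "")
  invisible(x)
}

#' Read / write depth profiles as CSV
#'
#' CSV columns are `depth_um` and `po2_mmHg`; the surface pO2, when known,
#' travels in the accompanying configuration rather than the table.
#'
#' @param path CSV file path.
#' @param surface_po2 Optional supply pO2 passed through to [depth_profile()].
#' @return [read_depth_profile()] returns a `depth_profile`;
#'   [write_depth_profile()] returns `path` invisibly.
#' @export
read_depth_profile <- function(path, surface_po2 = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("depth_um", "po2_mmHg") %in% names(d))) {
    stop("expected columns `depth_um` and `po2_mmHg` in ", path, call. = FALSE)
  }
  depth_profile(d$depth_um, d$po2_mmHg, surface_po2 = surface_po2)
}

#' @rdname read_depth_profile
#' @param profile A `depth_profile`.
#' @export
write_depth_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  utils::write.csv(data.frame(depth_um = profile$depth,
                              po2_mmHg = profile$po2),
                   path, row.names = FALSE)
  invisible(path)
}

#' Estimate CMRO2 from an oxygen depth profile
#'
#' Treats the (depth-homogeneous) CMRO2 as the single adjustable parameter of
#' the planar reaction-diffusion model and minimizes the unweighted sum of
#' squared differences between the forward solution and the measured pO2 at
#' the recorded depths, by Brent scalar minimization on `[0, m_max]`.
#'
#' Boundary handling follows the acquisition design:
#' * **three-point** (`surface_po2` known, from the profile or `params`): the
#'   supplied supply value is the Dirichlet boundary and every record enters
#'   the residual sum;
#' * **multi-step** (no supply value): the shallowest measurement is used as
#'   the Dirichlet value, anchored at its own depth, and excluded from the
#'   residuals.
#'
#' @param profile A [depth_profile()].
#' @param params Optional [slice_model_params()]. When supplied its
#'   `domain_depth` must equal the profile's core depth and its `surface_po2`
#'   is used as the boundary. When omitted, physical constants take their
#'   defaults and the boundary comes from the profile (see above).
#' @param m_max Upper search bound for CMRO2, mmHg/s.
#' @param tol Optimizer tolerance on CMRO2, mmHg/s.
#' @return A `cmro2_fit` object: `estimate` (mmHg/s), `sse` (mmHg^2),
#'   `n_points` (residual count), `converged`, `boundary_hit`
#'   (`NA`, `"lower"` or `"upper"`), and `search_bounds`.
#' @examples
#' sp <- slice_model_params(surface_po2 = 400, domain_depth = 160)
#' truth <- solve_planar_steady_state(sp, cmro2 = 40)
#' prof <- depth_profile(c(40, 100, 160), truth$po2[c(41, 101, 161)],
#'                       surface_po2 = 400)
#' fit_cmro2(prof)$estimate
#' @export
fit_cmro2 <- function(profile, params = NULL, m_max = 500, tol = 1e-3) {
  stopifnot(inherits(profile, "depth_profile"))
  check_positive_scalar(m_max, "m_max")

  surface <- if (!is.null(params)) {
    stopifnot(inherits(params, "slice_model_params"))
    if (abs(params$domain_depth - profile$core_depth) > 1e-9) {
      stop("`params$domain_depth` (", params$domain_depth,
           ") must equal the profile core depth (", profile$core_depth, ")",
           call. = FALSE)
    }
    params$surface_po2
  } else {
    profile$surface_po2
  }

  if (is.null(surface)) {
    # multi-step design: anchor on the shallowest measurement
    fit_depth <- profile$depth[-1] - profile$depth[1]
    fit_po2 <- profile$po2[-1]
    sp <- remake_slice_params(params, surface_po2 = profile$po2[1],
                              domain_depth = profile$core_depth - profile$depth[1])
  } else {
    fit_depth <- profile$depth
    fit_po2 <- profile$po2
    sp <- remake_slice_params(params, surface_po2 = surface,
                              domain_depth = profile$core_depth)
  }

  obj <- function(m) {
    f <- solve_planar_steady_state(sp, m)
    pred <- stats::approx(f$positions, f$po2, xout = fit_depth)$y
    sum((pred - fit_po2)^2)
  }
  opt <- stats::optimize(obj, interval = c(0, m_max), tol = tol)
  est <- opt$minimum
  boundary_hit <- if (est <= 10 * tol && obj(0) <= opt$objective) "lower"
                  else if (est >= m_max - 10 * tol) "upper"
                  else NA_character_
  structure(list(estimate = est, sse = opt$objective,
                 n_points = length(fit_po2),
                 converged = is.na(boundary_hit), boundary_hit = boundary_hit,
                 search_bounds = c(0, m_max), surface_po2 = sp$surface_po2,
                 core_depth = profile$core_depth),
            class = "cmro2_fit")
}

# rebuild slice params with a new boundary/domain, keeping physical constants
remake_slice_params <- function(params, surface_po2, domain_depth) {
  if (is.null(params)) {
    slice_model_params(surface_po2 = surface_po2, domain_depth = domain_depth)
  } else {
    slice_model_params(surface_po2 = surface_po2, domain_depth = domain_depth,
                       diffusion_constant = params$diffusion_constant,
                       km = params$km,
                       layer_thickness = params$layer_thickness)
  }
}

#' @export
print.cmro2_fit <- function(x, ...) {
  cat("CMRO2 fit: ", format(round(x$estimate, 3)), " mmHg/s (SSE ",
      format(signif(x$sse, 4)), " mmHg^2, ", x$n_points, " points",
      if (!x$converged) paste0(", boundary hit: ", x$boundary_hit), ")\n",
      sep = "")
  invisible(x)
}

#' Time-resolved CMRO2 from three-point pO2 traces
#'
#' Under the quasi-steady-state assumption, each time sample of the three
#' fixed-depth pO2 channels is treated as an instantaneous depth profile and
#' fitted independently with [fit_cmro2()]. Channels are first smoothed with a
#' centered moving average (default 1 s; the diffusional equilibration time of
#' the slice, roughly L^2/D ~ 16 s for a 160-um core depth, limits how fast
#' true CMRO2 changes can be tracked and is not corrected for). The core depth
#' is held fixed at the deepest electrode position throughout.
#'
#' @param traces A [trace_set()] with at least 3 pO2 channels.
#' @param params A [slice_model_params()]; its `domain_depth` must equal the
#'   deepest electrode depth and its `surface_po2` supplies the Dirichlet
#'   boundary (the chamber supply value).
#' @param smooth_window_s Width of the centered moving average, s (0 disables).
#' @param baseline_window Two-element numeric, the pre-onset window (s) whose
#'   median fitted CMRO2 defines the baseline. Default: the first 30 s.
#' @inheritParams fit_cmro2
#' @return A `cmro2_series` object: `times` (s), `estimates` (mmHg/s),
#'   `baseline` (mmHg/s), `baseline_window`, and per-sample convergence flags.
#' @seealso [excess_cmro2_auc()]
#' @export
fit_cmro2_timeseries <- function(traces, params, smooth_window_s = 1,
                                 baseline_window = NULL, m_max = 500,
                                 tol = 1e-3) {
  stopifnot(inherits(traces, "trace_set"), inherits(params, "slice_model_params"))
  if (length(traces$time) == 0L) stop("empty trace set", call. = FALSE)
  depths <- traces$po2_depths
  if (length(depths) < 3L) {
    stop("time-resolved fitting needs at least 3 pO2 channels", call. = FALSE)
  }
  core <- max(depths)
  if (any(depths < 0)) stop("electrode depths must be non-negative",
                            call. = FALSE)
  if (abs(params$domain_depth - core) > 1e-9) {
    stop("`params$domain_depth` (", params$domain_depth,
         ") must equal the deepest electrode depth (", core, ")",
         call. = FALSE)
  }
  if (is.null(baseline_window)) {
    baseline_window <- c(traces$time[1], traces$time[1] + 30)
  }

  po2 <- traces$po2
  if (smooth_window_s > 0) {
    w <- max(1L, as.integer(round(smooth_window_s * traces$sampling_rate)))
    po2 <- apply(po2, 2, moving_average, width = w)
  }

  nt <- length(traces$time)
  est <- numeric(nt)
  conv <- logical(nt)
  # interpolation weights of the electrode depths on the solver grid
  h <- params$layer_thickness
  pos <- depths / h
  lo <- pmin(floor(pos), params$n_layers - 1L)
  frac <- pos - lo
  obj <- function(m, y) {
    p <- .planar_solve_cpp(params$surface_po2, params$n_layers, h,
                           params$diffusion_constant, params$km, m,
                           1e-6, 10000L)
    pred <- p[lo + 1L] * (1 - frac) + p[lo + 2L] * frac
    sum((pred - y)^2)
  }
  for (i in seq_len(nt)) {
    y <- pmax(po2[i, ], 0)
    opt <- stats::optimize(obj, interval = c(0, m_max), tol = tol, y = y)
    est[i] <- opt$minimum
    conv[i] <- opt$minimum > 10 * tol && opt$minimum < m_max - 10 * tol
  }

  in_bl <- traces$time >= baseline_window[1] & traces$time < baseline_window[2]
  if (!any(in_bl)) {
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         ") contains no samples", call. = FALSE)
  }
  structure(list(times = traces$time, estimates = est,
                 baseline = stats::median(est[in_bl]),
                 baseline_window = baseline_window, converged = conv),
            class = "cmro2_series")
}

#' @export
print.cmro2_series <- function(x, ...) {
  cat("CMRO2 series: ", length(x$times), " samples over [",
      format(x$times[1]), ", ", format(x$times[length(x$times)]), "] s\n",
      "  baseline ", format(round(x$baseline, 2)), " mmHg/s, peak ",
      format(round(max(x$estimates), 2)), " mmHg/s\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cmro2_series <- function(x, ...) {
  data.frame(time_s = x$times, cmro2_mmHg_s = x$estimates,
             baseline_mmHg_s = x$baseline)
}

#' Cumulative excess CMRO2 over a post-onset horizon
#'
#' Integrates `max(estimate - baseline, 0)` over `[onset, onset + horizon]`
#' by the trapezoidal rule (mmHg, since mmHg/s x s). This is the cumulative
#' oxygen consumption attributable to the event beyond baseline metabolism.
#'
#' @param series A `cmro2_series` from [fit_cmro2_timeseries()].
#' @param onset Event onset time, s.
#' @param horizon Integration horizon after onset, s.
#' @return Non-negative scalar AUC, mmHg.
#' @export
excess_cmro2_auc <- function(series, onset, horizon = 300) {
  stopifnot(inherits(series, "cmro2_series"))
  check_positive_scalar(horizon, "horizon")
  t_end <- onset + horizon
  tmax <- series$times[length(series$times)]
  if (tmax < t_end) {
    stop("series ends at ", tmax, " s but the horizon requires ", t_end,
         " s (", t_end - tmax, " s short)", call. = FALSE)
  }
  if (series$times[1] > onset) {
    stop("series starts after the requested onset", call. = FALSE)
  }
  excess <- pmax(series$estimates - series$baseline, 0)
  # resample onto [onset, t_end] with exact endpoints
  keep <- series$times > onset & series$times < t_end
  tt <- c(onset, series$times[keep], t_end)
  yy <- c(stats::approx(series$times, excess, xout = onset)$y,
          excess[keep],
          stats::approx(series$times, excess, xout = t_end)$y)
  sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
}

# centered moving average with edge replication
moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  half <- width %/% 2L
  padded <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(padded, rep(1 / (2L * half + 1L), 2L * half + 1L),
                           sides = 2))[(half + 1L):(half + length(x))]
}
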