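#' Nernst calibration for a potassium-sensitive electrode
#'
#' Ion-sensitive electrodes report a voltage proportional to the log of the
#' ion activity; the decade slope is ideally `ln(10) R T / F` (about
#' 61.3 mV/decade at 36 C) but is calibrated per electrode in practice, so it
#' is configurable. Conversion anchors on an assumed resting extracellular
#' potassium of 3 mM.
#'
#' @param baseline_k Resting extracellular potassium, mM.
#' @param temperature Recording temperature, K.
#' @param slope mV per decade of concentration; default the ideal Nernst
#'   slope at `temperature`.
#' @return A `nernst_calibration` object.
#' @examples
#' nernst_calibration()$slope  # ~61.3 mV/decade at 36 C
#' @export
nernst_calibration <- function(baseline_k = 3, temperature = 309.15,
                               slope = NULL) {
  check_positive_scalar(baseline_k, "baseline_k")
  check_positive_scalar(temperature, "temperature")
  if (is.null(slope)) {
    # ln(10) * R * T / F, in mV
    slope <- log(10) * 8.314462618 * temperature / 96485.33212 * 1000
  }
  check_positive_scalar(slope, "slope")
  structure(list(baseline_k = baseline_k, temperature = temperature,
                 slope = slope),
            class = "nernst_calibration")
}

#' Convert electrode voltage to extracellular potassium and back
#'
#' `[K+]o(t) = baseline_k * 10^(dv(t)/slope)` where `dv` is the voltage
#' relative to the trace's baseline. The inverse map
#' `v = slope * log10(k / baseline_k)` recovers the relative voltage exactly.
#'
#' @param v Electrode voltage trace, mV.
#' @param calib A [nernst_calibration()].
#' @param baseline_mv Baseline voltage subtracted before conversion. If
#'   `NULL`, the median of the first 10% of samples is used; supply the
#'   median over a 30-s pre-event window when the event time is known.
#' @return Potassium concentration trace, mM (strictly positive).
#' @examples
#' cal <- nernst_calibration()
#' voltage_to_potassium(c(0, cal$slope), cal, baseline_mv = 0)  # 3, 30 mM
#' @export
voltage_to_potassium <- function(v, calib = nernst_calibration(),
                                 baseline_mv = NULL) {
  stopifnot(inherits(calib, "nernst_calibration"))
  if (length(v) == 0L) stop("empty voltage trace", call. = FALSE)
  if (is.null(baseline_mv)) {
    baseline_mv <- stats::median(v[seq_len(max(1L, round(0.1 * length(v))))])
  }
  calib$baseline_k * 10^((v - baseline_mv) / calib$slope)
}

#' @rdname voltage_to_potassium
#' @param k Potassium concentration trace, mM (> 0).
#' @export
potassium_to_voltage <- function(k, calib = nernst_calibration()) {
  stopifnot(inherits(calib, "nernst_calibration"))
  if (length(k) == 0L) stop("empty concentration trace", call. = FALSE)
  if (any(k <= 0)) stop("concentrations must be positive", call. = FALSE)
  calib$slope * log10(k / calib$baseline_k)
}

#' Construct a multi-channel SD recording
#'
#' Bundles the simultaneously acquired channels of one slice recording: the
#' DC local field potential, the potassium electrode (either raw voltage or
#' already-converted concentration), and pO2 at named depths, all on one
#' strictly uniform time base.
#'
#' @param time Sample times, s, strictly uniform.
#' @param dc DC potential, mV.
#' @param po2 Matrix or data frame of pO2 channels (mmHg), one column per
#'   electrode depth.
#' @param po2_depths Electrode depths in um, one per pO2 column.
#' @param k_voltage Potassium-electrode voltage, mV (optional if `k` given).
#' @param k Potassium concentration, mM (optional if `k_voltage` given).
#' @return A `trace_set` object with `sampling_rate` (Hz) derived from `time`.
#' @export
trace_set <- function(time, dc, po2, po2_depths, k_voltage = NULL, k = NULL) {
  if (length(time) < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * stats::median(dt)) {
    stop("time base must be strictly uniform", call. = FALSE)
  }
  po2 <- as.matrix(po2)
  if (length(po2_depths) != ncol(po2)) {
    stop("`po2_depths` must name every pO2 column", call. = FALSE)
  }
  if (is.null(k_voltage) && is.null(k)) {
    stop("one of `k_voltage` (mV) or `k` (mM) is required", call. = FALSE)
  }
  n <- length(time)
  lens <- c(length(dc), nrow(po2),
            if (!is.null(k_voltage)) length(k_voltage),
            if (!is.null(k)) length(k))
  if (any(lens != n)) stop("all channels must match the time base length",
                           call. = FALSE)
  colnames(po2) <- paste0("po2_", po2_depths, "um")
  structure(list(time = time, dc = dc, po2 = po2,
                 po2_depths = as.numeric(po2_depths),
                 k_voltage = k_voltage, k = k,
                 sampling_rate = 1 / stats::median(dt)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("SD trace set: ", length(x$time), " samples at ",
      format(round(x$sampling_rate, 3)), " Hz, pO2 depths ",
      paste(x$po2_depths, collapse = "/"), " um, K channel: ",
      if (!is.null(x$k)) "mM" else "mV", "\n", sep = "")
  invisible(x)
}

#' Read / write trace sets as CSV
#'
#' Column layout: `time_s`, `dc_mV`, one of `k_mV` / `k_mM`, and
#' `po2_<depth>um_mmHg` for each oxygen electrode.
#'
#' @param path CSV file path.
#' @return [read_trace_set()] returns a `trace_set`; [write_trace_set()]
#'   returns `path` invisibly.
#' @export
read_trace_set <- function(path) {
  d <- utils::read.csv(path)
  po2_cols <- grep("^po2_[0-9.]+um_mmHg$", names(d), value = TRUE)
  if (!"time_s" %in% names(d) || !"dc_mV" %in% names(d) ||
      length(po2_cols) == 0L) {
    stop("expected columns time_s, dc_mV and po2_<depth>um_mmHg in ", path,
         call. = FALSE)
  }
  depths <- as.numeric(sub("^po2_([0-9.]+)um_mmHg$", "\\1", po2_cols))
  trace_set(time = d$time_s, dc = d$dc_mV,
            po2 = d[po2_cols], po2_depths = depths,
            k_voltage = if ("k_mV" %in% names(d)) d$k_mV,
            k = if ("k_mM" %in% names(d)) d$k_mM)
}

#' @rdname read_trace_set
#' @param traces A `trace_set`.
#' @export
write_trace_set <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  d <- data.frame(time_s = traces$time, dc_mV = traces$dc)
  if (!is.null(traces$k_voltage)) d$k_mV <- traces$k_voltage
  if (!is.null(traces$k)) d$k_mM <- traces$k
  po2 <- traces$po2
  colnames(po2) <- paste0("po2_", traces$po2_depths, "um_mmHg")
  utils::write.csv(cbind(d, po2), path, row.names = FALSE)
  invisible(path)
}

#' Detect spreading-depolarization onset from the DC channel
#'
#' The onset is the first time the DC potential falls below
#' `baseline mean - max(k_sd * baseline SD, floor_mv)` and stays below for at
#' least `sustain_s` seconds. The absolute floor guards against noise-free or
#' very quiet baselines; the SD-associated negative DC shift is an order of
#' magnitude larger than either bound.
#'
#' @param time Sample times, s.
#' @param dc DC potential, mV.
#' @param baseline_window Two-element window (s) preceding the event used to
#'   estimate baseline mean and SD. Default: the first 30 s of the trace.
#' @param k_sd Multiplier on the baseline SD.
#' @param floor_mv Absolute deflection floor, mV.
#' @param sustain_s Minimum time the trace must stay below threshold, s.
#' @return Onset time (s), or `NA` when no SD is detected (a valid outcome,
#'   distinct from the error raised when the baseline window is missing).
#' @export
detect_sd_onset <- function(time, dc, baseline_window = NULL, k_sd = 5,
                            floor_mv = 2, sustain_s = 2) {
  if (length(time) == 0L || length(dc) != length(time)) {
    stop("`time` and `dc` must be non-empty and of equal length", call. = FALSE)
  }
  if (is.null(baseline_window)) baseline_window <- c(time[1], time[1] + 30)
  in_bl <- time >= baseline_window[1] & time < baseline_window[2]
  if (!any(in_bl)) {
    stop("baseline window [", baseline_window[1], ", ", baseline_window[2],
         ") contains no samples (trace may start mid-event)", call. = FALSE)
  }
  bl <- dc[in_bl]
  threshold <- mean(bl) - max(k_sd * stats::sd(bl), floor_mv)
  below <- dc < threshold
  below[is.na(below)] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- stats::median(diff(time))
  for (i in seq_along(r$values)) {
    if (r$values[i] && (r$lengths[i] - 1L) * dt >= sustain_s - 1e-9) {
      return(time[starts[i]])
    }
  }
  NA_real_
}

#' Extract per-event SD features from a multi-channel recording
#'
#' Computes the descriptors used to characterize a spreading-depolarization
#' episode:
#' * `dc_amplitude` - baseline-to-trough magnitude of the negative DC shift;
#' * `dc_duration` - full width at the configurable fraction (default half)
#'   of the maximal negative amplitude, with sub-sample linear interpolation
#'   of the crossings;
#' * `delta_k` - potassium peak minus baseline, mM;
#' * `t1_50`, `t2_50` - times from the potassium peak until decay to 50% and
#'   10% of `delta_k` above baseline (interpolated); `t2_50` is reported as
#'   `NA` with `t2_50_censored = TRUE` when the trace ends first;
#' * `min_po2` - per-channel pO2 minimum over the post-onset window;
#' * `hypoxia` - whether the deepest (core) channel falls below the hypoxia
#'   threshold.
#'
#' Baselines for the DC and potassium channels are medians over the 30 s
#' preceding onset. All features are invariant to constant DC offsets and to
#' uniform time shifts.
#'
#' @param traces A [trace_set()].
#' @param calib A [nernst_calibration()]; used when the potassium channel is
#'   recorded as voltage.
#' @param onset Event onset, s. When `NULL` it is detected with
#'   [detect_sd_onset()]; if none is found the return value has
#'   `detected = FALSE` and no features.
#' @param post_window_s Feature window after onset, s.
#' @param threshold Hypoxia threshold for the core channel, mmHg.
#' @param duration_fraction Fraction of peak negative amplitude defining the
#'   DC duration (0.5 = full width at half maximum).
#' @param baseline_s Length of the pre-onset baseline window, s.
#' @return An `sd_features` object.
#' @export
extract_sd_features <- function(traces, calib = nernst_calibration(),
                                onset = NULL, post_window_s = 300,
                                threshold = 8, duration_fraction = 0.5,
                                baseline_s = 30) {
  stopifnot(inherits(traces, "trace_set"))
  time <- traces$time

  if (is.null(onset)) {
    onset <- detect_sd_onset(time, traces$dc)
    if (is.na(onset)) {
      return(structure(list(detected = FALSE), class = "sd_features"))
    }
  }

  pre <- time >= onset - baseline_s & time < onset
  if (!any(pre)) stop("no samples in the pre-onset baseline window",
                      call. = FALSE)
  win <- time >= onset & time <= onset + post_window_s

  # --- DC shift ---
  dc_bl <- stats::median(traces$dc[pre])
  defl <- dc_bl - traces$dc          # positive = negative shift
  trough_i <- which(win)[which.max(defl[win])]
  dc_amplitude <- max(defl[trough_i], 0)
  level <- duration_fraction * dc_amplitude
  dc_duration <- width_at_level(time, defl, trough_i, level)

  # --- potassium transient ---
  k <- traces$k
  if (is.null(k)) {
    k <- voltage_to_potassium(traces$k_voltage, calib,
                              baseline_mv = stats::median(traces$k_voltage[pre]))
  }
  k_bl <- stats::median(k[pre])
  peak_i <- which(win)[which.max(k[win])]
  delta_k <- max(k[peak_i] - k_bl, 0)
  t1_50 <- decay_time(time, k, peak_i, k_bl + 0.5 * delta_k)
  t2 <- decay_time(time, k, peak_i, k_bl + 0.1 * delta_k)

  # --- oxygen ---
  min_po2 <- apply(traces$po2[win, , drop = FALSE], 2, min)
  names(min_po2) <- paste0(traces$po2_depths, "um")
  core_min <- min_po2[[which.max(traces$po2_depths)]]

  structure(list(
    detected = TRUE, onset = onset,
    dc_amplitude = dc_amplitude, dc_duration = dc_duration,
    delta_k = delta_k, t1_50 = t1_50,
    t2_50 = if (is.na(t2)) NA_real_ else t2, t2_50_censored = is.na(t2),
    min_po2 = min_po2, core_min_po2 = core_min,
    hypoxia = core_min < threshold, threshold = threshold),
    class = "sd_features")
}

# width of the deflection around index `peak_i` at height `level`,
# with linear interpolation of both crossings
width_at_level <- function(time, defl, peak_i, level) {
  n <- length(defl)
  i <- peak_i
  while (i > 1L && defl[i - 1L] >= level) i <- i - 1L
  t_on <- if (i == 1L) time[1] else {
    cross_time(time[i - 1L], time[i], defl[i - 1L], defl[i], level)
  }
  j <- peak_i
  while (j < n && defl[j + 1L] >= level) j <- j + 1L
  t_off <- if (j == n) time[n] else {
    cross_time(time[j], time[j + 1L], defl[j], defl[j + 1L], level)
  }
  t_off - t_on
}

# time from the peak until the trace first decays to `level` (interpolated);
# NA when it never does within the trace
decay_time <- function(time, x, peak_i, level) {
  n <- length(x)
  for (i in seq(peak_i, n - 1L)) {
    if (x[i + 1L] <= level) {
      return(cross_time(time[i], time[i + 1L], x[i], x[i + 1L], level) -
               time[peak_i])
    }
  }
  NA_real_
}

cross_time <- function(t0, t1, y0, y1, level) {
  if (y1 == y0) return(t1)
  t0 + (level - y0) / (y1 - y0) * (t1 - t0)
}

#' @export
print.sd_features <- function(x, ...) {
  if (!x$detected) {
    cat("SD features: no SD detected\n")
    return(invisible(x))
  }
  cat("SD features (onset ", format(round(x$onset, 2)), " s)\n",
      "  DC: amplitude ", format(round(x$dc_amplitude, 2)), " mV, duration ",
      format(round(x$dc_duration, 2)), " s\n",
      "  [K+]o: delta ", format(round(x$delta_k, 2)), " mM, T1_50 ",
      format(round(x$t1_50, 2)), " s, T2_50 ",
      if (x$t2_50_censored) "censored" else format(round(x$t2_50, 2)),
      " s\n  core min pO2 ", format(round(x$core_min_po2, 2)), " mmHg (",
      if (x$hypoxia) "hypoxic" else "above threshold", ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sd_features <- function(x, ...) {
  if (!x$detected) return(data.frame(detected = FALSE))
  cbind(data.frame(detected = TRUE, onset_s = x$onset,
                   dc_amplitude_mV = x$dc_amplitude,
                   dc_duration_s = x$dc_duration, delta_k_mM = x$delta_k,
                   t1_50_s = x$t1_50, t2_50_s = x$t2_50,
                   t2_50_censored = x$t2_50_censored,
                   hypoxia = x$hypoxia),
        as.data.frame(as.list(stats::setNames(
          x$min_po2, paste0("min_po2_", names(x$min_po2), "_mmHg")))))
}

#' Convert an isoflurane vapor concentration to aqueous concentration
#'
#' `mM = percent/100 * (1000 / molar_volume) * partition_coefficient`: the
#' vapor fraction is converted to a gas-phase concentration via the molar
#' volume and scaled by the water/gas partition coefficient. The default
#' molar volume of 22.711 L/mol (ideal gas at 0 C, 100 kPa) together with the
#' 0.5424 partition coefficient reproduces the standard reported conversions
#' 1% -> 0.24 mM and 3% -> 0.72 mM at two decimals; see the package vignette
#' for the sensitivity of the second decimal to this convention.
#'
#' @param percent Vapor concentration, vol% (>= 0).
#' @param partition_coefficient Water/gas partition coefficient at 37 C.
#' @param molar_volume Gas molar volume, L/mol.
#' @param digits Decimal places for the reported value; use `NULL` for full
#'   precision.
#' @return Aqueous isoflurane concentration, mM. Conversion is strictly
#'   linear in `percent`.
#' @examples
#' isoflurane_percent_to_mM(c(1, 3))  # 0.24, 0.72
#' @export
isoflurane_percent_to_mM <- function(percent, partition_coefficient = 0.5424,
                                     molar_volume = 22.711, digits = 2) {
  if (any(percent < 0)) stop("`percent` must be non-negative", call. = FALSE)
  check_positive_scalar(partition_coefficient, "partition_coefficient")
  check_positive_scalar(molar_volume, "molar_volume")
  mm <- percent / 100 * (1000 / molar_volume) * partition_coefficient
  if (is.null(digits)) mm else round(mm, digits)
}
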