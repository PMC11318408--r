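#' Default configuration for a full synthetic SD study
#'
#' Assembles every tunable of the end-to-end analysis in one nested list:
#' slice model constants, the electrode layout, per-condition scenarios
#' (control plus any number of treatments), the Krogh-map scan grids, and
#' cohort size. Values not overridden keep the study-condition defaults.
#'
#' @param n_slices Cohort size (slices, each measured under every condition).
#' @param seed Root seed for all randomness in the run.
#' @param scenarios Named list of [sd_scenario()] objects; must contain
#'   `control`. Default: `control` (aCSF medians) and `iso3` (3% isoflurane
#'   medians: lower SD CMRO2, smaller potassium transient, longer DC shift
#'   and decay landmarks).
#' @param map_cmro2 Named numeric vector of CMRO2 levels (mmHg/s) for the
#'   oxygenation maps.
#' @param ... Overrides merged into the defaults (shallow).
#' @return A named list (class `sd_study_config`).
#' @export
sd_study_config <- function(n_slices = 12, seed = 1L, scenarios = NULL,
                            map_cmro2 = NULL, ...) {
  if (is.null(scenarios)) {
    scenarios <- list(
      control = sd_scenario(),
      iso3 = sd_scenario(baseline_cmro2 = 34.7 / 38.9 * 34.4,
                         peak_ratio = 1 + 18.4 / 34.4,
                         dc_duration = 107, delta_k = 16.5,
                         t1_50 = 38.3, t2_50 = 235.7))
  }
  if (!"control" %in% names(scenarios)) {
    stop("`scenarios` must contain a `control` entry", call. = FALSE)
  }
  if (is.null(map_cmro2)) {
    map_cmro2 <- c(baseline = 34.4, sd = 92.0)
  }
  cfg <- utils::modifyList(list(
    n_slices = n_slices, seed = as.integer(seed), scenarios = scenarios,
    slice = list(surface_po2 = 400, domain_depth = 160, km = 3,
                 diffusion_constant = 1600),
    depths = c(40, 100, 160),
    multistep_depths = seq(0, 160, by = 20),
    krogh = list(capillary_po2_grid = 20:55, radius_grid = 10:35,
                 capillary_radius = 2.5, threshold = 8),
    map_cmro2 = map_cmro2,
    auc_horizon = 300,
    m_comparisons = max(1L, length(scenarios) - 1L)),
    list(...))
  class(cfg) <- "sd_study_config"
  cfg
}

#' Read a study configuration from YAML or JSON
#'
#' Reads a serialized configuration (see the example shipped at
#' `system.file("extdata", "example_study.yaml", package = "oxyslice")`) and
#' turns every entry under `scenarios` into an [sd_scenario()]. Scenario
#' CMRO2 levels, transient landmarks and map grids are plain data in the
#' file, never hard-coded.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return An [sd_study_config()].
#' @export
read_study_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configuration requires the `yaml` package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  scenarios <- lapply(raw$scenarios, function(s) do.call(sd_scenario, s))
  # grids may be written compactly as {from, to, by}
  if (!is.null(raw$krogh)) {
    raw$krogh <- lapply(raw$krogh, function(x) {
      if (is.list(x) && all(c("from", "to") %in% names(x))) {
        seq(x$from, x$to, by = if (is.null(x$by)) 1 else x$by)
      } else x
    })
  }
  extra <- raw[setdiff(names(raw), c("scenarios", "map_cmro2"))]
  do.call(sd_study_config,
          c(list(scenarios = scenarios,
                 map_cmro2 = unlist(raw$map_cmro2)),
            extra))
}

#' Run the full synthetic SD study
#'
#' Deterministic end-to-end driver: (1) baseline depth-profile fits comparing
#' the multi-step and three-point designs on the same synthetic slice;
#' (2) one demonstration episode per condition with time-resolved CMRO2,
#' excess-CMRO2 AUC and per-event SD features; (3) a paired feature cohort
#' and signed-rank comparisons of every treatment against control (Bonferroni
#' over the planned treatment-vs-control contrasts); (4) perivascular
#' oxygenation maps with hypoxia boundaries per CMRO2 level. Stages run
#' independently: a failure in one is recorded in `$errors` and the rest
#' still complete.
#'
#' @param config An [sd_study_config()].
#' @param out_dir Optional directory; when given, every table is written
#'   under `fits/`, `features/`, `maps/`, `stats/` plus a `report.json`
#'   carrying the provenance block (config hash, seed, package version).
#' @return A `sd_study_report` list with elements `design_comparison`,
#'   `episodes`, `cohort`, `comparisons`, `maps`, `provenance`, `errors`.
#' @export
run_sd_study <- function(config = sd_study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sd_study_config"))
  errors <- list()
  note_error <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }
  sp <- slice_model_params(surface_po2 = config$slice$surface_po2,
                           domain_depth = config$slice$domain_depth,
                           diffusion_constant = config$slice$diffusion_constant,
                           km = config$slice$km)

  # --- stage 1: multi-step vs three-point design comparison -----------------
  design <- tryCatch({
    truth <- config$scenarios$control$baseline_cmro2
    multi <- generate_depth_profile(truth, sp, config$multistep_depths,
                                    noise_sd = 1, seed = config$seed)
    multi$surface_po2 <- NULL          # multi-step fits anchor on the data
    three <- generate_depth_profile(truth, sp, config$depths,
                                    noise_sd = 1, seed = config$seed + 1L)
    f_multi <- fit_cmro2(multi)
    f_three <- fit_cmro2(three, params = sp)
    data.frame(design = c("multi_step", "three_point"),
               true_cmro2 = truth,
               estimate = c(f_multi$estimate, f_three$estimate),
               sse = c(f_multi$sse, f_three$sse),
               n_points = c(f_multi$n_points, f_three$n_points))
  }, error = function(e) note_error("design_comparison", e))

  # --- stage 2: demonstration episodes per condition ------------------------
  episodes <- tryCatch({
    lapply(stats::setNames(nm = names(config$scenarios)), function(nm) {
      sc <- config$scenarios[[nm]]
      ep <- generate_sd_episode(sc, params = sp, depths = config$depths,
                                seed = config$seed + match(nm, names(config$scenarios)))
      feats <- extract_sd_features(ep)
      series <- fit_cmro2_timeseries(ep, sp,
                                     baseline_window = c(0, sc$onset))
      auc <- excess_cmro2_auc(series, onset = feats$onset,
                              horizon = config$auc_horizon)
      list(condition = nm, features = feats, series = series,
           excess_auc = auc,
           ground_truth = attr(ep, "ground_truth"))
    })
  }, error = function(e) note_error("episodes", e))

  # --- stage 3: paired cohort and statistics --------------------------------
  cohort <- NULL
  comparisons <- tryCatch({
    treatments <- setdiff(names(config$scenarios), "control")
    out <- list()
    for (i in seq_along(treatments)) {
      trt <- treatments[i]
      coh <- generate_paired_cohort(config$scenarios$control,
                                    config$scenarios[[trt]],
                                    n_slices = config$n_slices,
                                    seed = config$seed + 100L + i)
      if (is.null(cohort)) cohort <- coh
      ctrl <- coh[coh$condition == "control", ]
      trtd <- coh[coh$condition == "treated", ]
      for (feat in c("sd_cmro2", "delta_k", "dc_duration", "t1_50", "t2_50")) {
        cmp <- paired_comparison(ctrl[[feat]], trtd[[feat]],
                                 labels = c("control", trt),
                                 m_comparisons = config$m_comparisons)
        row <- cbind(data.frame(feature = feat), as.data.frame(cmp))
        out[[length(out) + 1L]] <- row
      }
    }
    do.call(rbind, out)
  }, error = function(e) note_error("comparisons", e))

  # --- stage 4: oxygenation maps --------------------------------------------
  maps <- tryCatch({
    lapply(stats::setNames(nm = names(config$map_cmro2)), function(nm) {
      oxygenation_map(capillary_po2_grid = config$krogh$capillary_po2_grid,
                      radius_grid = config$krogh$radius_grid,
                      cmro2 = config$map_cmro2[[nm]],
                      threshold = config$krogh$threshold,
                      capillary_radius = config$krogh$capillary_radius,
                      diffusion_constant = config$slice$diffusion_constant,
                      km = config$slice$km)
    })
  }, error = function(e) note_error("maps", e))

  provenance <- list(config_hash = config_hash(config), seed = config$seed,
                     package_version = as.character(utils::packageVersion("oxyslice")))
  report <- structure(list(design_comparison = design, episodes = episodes,
                           cohort = cohort, comparisons = comparisons,
                           maps = maps, provenance = provenance,
                           errors = errors),
                      class = "sd_study_report")
  if (!is.null(out_dir)) write_sd_study(report, config, out_dir)
  report
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_sd_study <- function(report, config, out_dir) {
  for (d in c("fits", "features", "maps", "stats")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  h <- report$provenance$config_hash
  stamp <- function(df) { df$config_hash <- h; df }
  if (!is.null(report$design_comparison)) {
    utils::write.csv(stamp(report$design_comparison),
                     file.path(out_dir, "fits", "design_comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$episodes)) {
    feats <- do.call(rbind, lapply(report$episodes, function(e) {
      cbind(data.frame(condition = e$condition,
                       excess_auc_mmHg = e$excess_auc,
                       baseline_cmro2_mmHg_s = e$series$baseline),
            as.data.frame(e$features))
    }))
    utils::write.csv(stamp(feats),
                     file.path(out_dir, "features", "episode_features.csv"),
                     row.names = FALSE)
    for (e in report$episodes) {
      utils::write.csv(stamp(as.data.frame(e$series)),
                       file.path(out_dir, "fits",
                                 paste0("cmro2_series_", e$condition, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(report$comparisons)) {
    utils::write.csv(stamp(report$comparisons),
                     file.path(out_dir, "stats", "paired_comparisons.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$maps)) {
    for (nm in names(report$maps)) {
      write_oxygenation_map(report$maps[[nm]],
                            file.path(out_dir, "maps", paste0(nm, ".csv")),
                            file.path(out_dir, "maps",
                                      paste0(nm, "_boundary.json")))
    }
  }
  jsonlite::write_json(c(report$provenance, list(errors = report$errors)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sd_study_report <- function(x, ...) {
  cat("SD study report (seed ", x$provenance$seed, ", config ",
      substr(x$provenance$config_hash, 1, 8), ")\n", sep = "")
  if (!is.null(x$design_comparison)) {
    d <- x$design_comparison
    cat("  design comparison: multi-step ",
        format(round(d$estimate[1], 2)), " vs three-point ",
        format(round(d$estimate[2], 2)), " mmHg/s (truth ",
        format(d$true_cmro2[1]), ")\n", sep = "")
  }
  if (!is.null(x$episodes)) {
    for (e in x$episodes) {
      cat("  episode [", e$condition, "]: peak CMRO2 ",
          format(round(max(e$series$estimates), 1)), " mmHg/s, excess AUC ",
          format(round(e$excess_auc)), " mmHg\n", sep = "")
    }
  }
  if (!is.null(x$comparisons)) {
    cat("  ", nrow(x$comparisons), " paired comparisons computed\n", sep = "")
  }
  if (length(x$errors)) {
    cat("  stage errors: ", paste(names(x$errors), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}
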