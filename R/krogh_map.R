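#' Minimal tissue pO2 in a Krogh cylinder
#'
#' The minimum of the steady-state perivascular field lies at the closed outer
#' edge of the cylinder (oxygen only enters through the capillary); this
#' returns that edge value.
#'
#' @param params A [krogh_params()] object.
#' @return Edge pO2 in mmHg.
#' @examples
#' minimal_ptio2(krogh_params(capillary_po2 = 20, outer_radius = 25,
#'                            cmro2 = 34.4))
#' @export
minimal_ptio2 <- function(params) {
  f <- solve_cylindrical_steady_state(params)
  f$po2[length(f$po2)]
}

#' Largest cylinder radius still oxygenated above the hypoxia threshold
#'
#' Scans outer radii (default 10-35 um in 1-um steps, matching the reported
#' range of perivascular diffusion distances) and returns the largest radius
#' whose edge pO2 strictly exceeds the hypoxia threshold (default ~8 mmHg,
#' the level at which oxidative metabolism fails). Radii are reported on the
#' scan grid, with no sub-grid interpolation.
#'
#' @param capillary_po2 Capillary pO2, mmHg.
#' @param cmro2 Tissue CMRO2, mmHg/s.
#' @param threshold Hypoxia threshold, mmHg (exceeded strictly).
#' @param radii Scan grid of outer radii, um, ascending.
#' @param capillary_radius,shell_thickness,diffusion_constant,km Passed to
#'   [krogh_params()].
#' @return The boundary radius in um. When even the largest scanned radius is
#'   above threshold the value is `Inf` with `status` attribute
#'   `"beyond_scan_range"`; when even the smallest is below it is `-Inf` with
#'   `status = "below_scan_range"`; otherwise `status = "within_scan_range"`.
#' @examples
#' hypoxia_boundary_radius(capillary_po2 = 20, cmro2 = 34.4)
#' @export
hypoxia_boundary_radius <- function(capillary_po2, cmro2, threshold = 8,
                                    radii = 10:35, capillary_radius = 2.5,
                                    shell_thickness = 1,
                                    diffusion_constant = 1600, km = 3) {
  if (length(radii) == 0L) stop("empty radius scan range", call. = FALSE)
  if (any(diff(radii) <= 0)) stop("`radii` must be ascending", call. = FALSE)
  edge <- vapply(radii, function(R) {
    minimal_ptio2(krogh_params(
      capillary_po2 = capillary_po2, outer_radius = R, cmro2 = cmro2,
      capillary_radius = capillary_radius, shell_thickness = shell_thickness,
      diffusion_constant = diffusion_constant, km = km))
  }, numeric(1))
  above <- edge > threshold
  if (all(above)) {
    structure(Inf, status = "beyond_scan_range")
  } else if (!above[1]) {
    structure(-Inf, status = "below_scan_range")
  } else {
    structure(radii[max(which(above))], status = "within_scan_range")
  }
}

#' Perivascular oxygenation map over capillary pO2 and cylinder radius
#'
#' Computes the minimal (edge) tissue pO2 of the Krogh cylinder for every
#' combination of capillary pO2 and outer radius, together with the
#' capillary-pO2-dependent hypoxia boundary (the largest radius still
#' supplied above threshold). This is the model's answer to "which
#' perivascular territory stays oxygenated at a given capillary pO2 and
#' metabolic rate".
#'
#' @param capillary_po2_grid Ascending capillary pO2 values, mmHg
#'   (default 20-55, the range reported for rodent cortical capillaries).
#' @param radius_grid Ascending outer radii, um (default 10-35).
#' @inheritParams hypoxia_boundary_radius
#' @return A `tissue_oxygenation_map`: `min_po2` is a matrix with one row per
#'   radius and one column per capillary pO2; `boundary_curve` gives, per
#'   capillary pO2, the hypoxia-boundary radius (with the
#'   [hypoxia_boundary_radius()] sentinel convention encoded as `Inf`/`-Inf`).
#' @examples
#' m <- oxygenation_map(capillary_po2_grid = c(20, 40), radius_grid = 10:20,
#'                      cmro2 = 34.4)
#' m$boundary_curve
#' @export
oxygenation_map <- function(capillary_po2_grid = 20:55, radius_grid = 10:35,
                            cmro2, threshold = 8, capillary_radius = 2.5,
                            shell_thickness = 1, diffusion_constant = 1600,
                            km = 3) {
  if (length(capillary_po2_grid) == 0L || length(radius_grid) == 0L) {
    stop("grids must be non-empty", call. = FALSE)
  }
  if (any(diff(capillary_po2_grid) <= 0) || any(diff(radius_grid) <= 0)) {
    stop("grids must be strictly ascending", call. = FALSE)
  }
  min_po2 <- matrix(NA_real_, nrow = length(radius_grid),
                    ncol = length(capillary_po2_grid),
                    dimnames = list(radius_grid, capillary_po2_grid))
  for (j in seq_along(capillary_po2_grid)) {
    for (i in seq_along(radius_grid)) {
      min_po2[i, j] <- minimal_ptio2(krogh_params(
        capillary_po2 = capillary_po2_grid[j], outer_radius = radius_grid[i],
        cmro2 = cmro2, capillary_radius = capillary_radius,
        shell_thickness = shell_thickness,
        diffusion_constant = diffusion_constant, km = km))
    }
  }
  boundary <- vapply(seq_along(capillary_po2_grid), function(j) {
    above <- min_po2[, j] > threshold
    if (all(above)) Inf
    else if (!above[1]) -Inf
    else radius_grid[max(which(above))]
  }, numeric(1))
  structure(list(capillary_po2_grid = capillary_po2_grid,
                 radius_grid = radius_grid, min_po2 = min_po2,
                 hypoxia_threshold = threshold, boundary_curve = boundary,
                 cmro2 = cmro2, capillary_radius = capillary_radius),
            class = "tissue_oxygenation_map")
}

#' @export
print.tissue_oxygenation_map <- function(x, ...) {
  cat("Tissue oxygenation map: ", length(x$capillary_po2_grid),
      " capillary pO2 x ", length(x$radius_grid), " radii, CMRO2 ",
      x$cmro2, " mmHg/s\n  hypoxia boundary (threshold ", x$hypoxia_threshold,
      " mmHg): ", format(x$boundary_curve[1]), " um at ",
      x$capillary_po2_grid[1], " mmHg -> ",
      format(x$boundary_curve[length(x$boundary_curve)]), " um at ",
      x$capillary_po2_grid[length(x$capillary_po2_grid)], " mmHg\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.tissue_oxygenation_map <- function(x, ...) {
  data.frame(
    capillary_po2_mmHg = rep(x$capillary_po2_grid, each = length(x$radius_grid)),
    radius_um = rep(x$radius_grid, times = length(x$capillary_po2_grid)),
    min_po2_mmHg = as.vector(x$min_po2))
}

#' Write an oxygenation map as long-format CSV plus a JSON boundary curve
#'
#' @param map A `tissue_oxygenation_map`.
#' @param csv_path Long-format CSV destination
#'   (`capillary_po2_mmHg, radius_um, min_po2_mmHg`).
#' @param json_path Optional JSON destination for the boundary curve and the
#'   parameters that produced it.
#' @return `csv_path`, invisibly.
#' @export
write_oxygenation_map <- function(map, csv_path, json_path = NULL) {
  stopifnot(inherits(map, "tissue_oxygenation_map"))
  utils::write.csv(as.data.frame(map), csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(capillary_po2_mmHg = map$capillary_po2_grid,
           boundary_radius_um = map$boundary_curve,
           hypoxia_threshold_mmHg = map$hypoxia_threshold,
           cmro2_mmHg_s = map$cmro2,
           capillary_radius_um = map$capillary_radius),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
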