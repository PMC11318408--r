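#' Physical parameters of the planar slice oxygen model
#'
#' Bundles the constants of the steady-state reaction-diffusion model used to
#' interpret partial tissue oxygen pressure (ptiO2) depth profiles in
#' interface-chamber brain slices. Oxygen enters through the slice surface
#' (held at the supply value), diffuses by Fick's law and is consumed by
#' Michaelis-Menten kinetics; the depth of the ptiO2 minimum acts as a closed
#' (zero-flux) boundary.
#'
#' @param surface_po2 Supply pO2 fixed at the slice surface, mmHg.
#' @param domain_depth Depth of the ptiO2 minimum (the closed boundary), um.
#'   Must be a whole multiple of `layer_thickness`.
#' @param diffusion_constant Oxygen diffusion constant in tissue, um^2/s.
#' @param km Michaelis constant of oxygen consumption, mmHg.
#' @param layer_thickness Discretization layer thickness, um.
#'
#' @return An object of class `slice_model_params`.
#' @examples
#' slice_model_params(surface_po2 = 150, domain_depth = 160)
#' @export
slice_model_params <- function(surface_po2, domain_depth,
                               diffusion_constant = 1600, km = 3,
                               layer_thickness = 1) {
  check_positive_scalar(surface_po2, "surface_po2")
  check_positive_scalar(domain_depth, "domain_depth")
  check_positive_scalar(diffusion_constant, "diffusion_constant")
  check_positive_scalar(km, "km")
  check_positive_scalar(layer_thickness, "layer_thickness")
  n_layers <- domain_depth / layer_thickness
  if (abs(n_layers - round(n_layers)) > 1e-9) {
    stop("`domain_depth` (", domain_depth,
         ") must be an integer multiple of `layer_thickness` (",
         layer_thickness, ")", call. = FALSE)
  }
  structure(
    list(surface_po2 = surface_po2, domain_depth = domain_depth,
         diffusion_constant = diffusion_constant, km = km,
         layer_thickness = layer_thickness,
         n_layers = as.integer(round(n_layers))),
    class = "slice_model_params")
}

#' Physical parameters of the Krogh perivascular cylinder
#'
#' Geometry and constants for the cylindrical tissue model: a central
#' capillary (lumen held at capillary pO2, a Dirichlet boundary at the vessel
#' wall) supplies a concentric tissue cylinder discretized into ~1-um shells;
#' no oxygen crosses the outer radius. All radii are measured from the
#' cylinder axis, so the cylinder radius includes the vessel compartment.
#'
#' When `(outer_radius - capillary_radius)` is not a whole multiple of
#' `shell_thickness`, the grid uses the nearest number of uniform shells that
#' spans the annulus exactly (shells of approximately `shell_thickness`).
#'
#' The default capillary radius of 2.5 um (a 5-um capillary, typical of rat
#' cortex) is a model choice, not a measured quantity, and materially shifts
#' the hypoxia-boundary radius; it is exposed here and recorded in every
#' oxygenation-map output.
#'
#' @param capillary_po2 pO2 in the capillary lumen, mmHg.
#' @param outer_radius Outer (closed) radius of the cylinder, um.
#' @param cmro2 Volumetric oxygen consumption rate at saturation, mmHg/s.
#' @param capillary_radius Radius of the vessel compartment, um.
#' @param shell_thickness Nominal tissue shell thickness, um.
#' @param diffusion_constant Oxygen diffusion constant, um^2/s.
#' @param km Michaelis constant, mmHg.
#'
#' @return An object of class `krogh_params`.
#' @examples
#' krogh_params(capillary_po2 = 20, outer_radius = 25, cmro2 = 34.4)
#' @export
krogh_params <- function(capillary_po2, outer_radius, cmro2,
                         capillary_radius = 2.5, shell_thickness = 1,
                         diffusion_constant = 1600, km = 3) {
  check_positive_scalar(capillary_po2, "capillary_po2")
  check_positive_scalar(outer_radius, "outer_radius")
  check_positive_scalar(capillary_radius, "capillary_radius")
  check_positive_scalar(shell_thickness, "shell_thickness")
  check_positive_scalar(diffusion_constant, "diffusion_constant")
  check_positive_scalar(km, "km")
  if (!is.numeric(cmro2) || length(cmro2) != 1L || is.na(cmro2) || cmro2 < 0) {
    stop("`cmro2` must be a non-negative number", call. = FALSE)
  }
  if (outer_radius <= capillary_radius) {
    stop("`outer_radius` (", outer_radius,
         ") must exceed `capillary_radius` (", capillary_radius, ")",
         call. = FALSE)
  }
  n_shells <- max(1L, as.integer(round(
    (outer_radius - capillary_radius) / shell_thickness)))
  structure(
    list(capillary_po2 = capillary_po2, outer_radius = outer_radius,
         cmro2 = cmro2, capillary_radius = capillary_radius,
         shell_thickness = shell_thickness,
         diffusion_constant = diffusion_constant, km = km,
         n_shells = n_shells),
    class = "krogh_params")
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop("`", name, "` must be a single positive number", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.slice_model_params <- function(x, ...) {
  cat("Planar slice oxygen model\n",
      "  surface pO2: ", x$surface_po2, " mmHg | depth: ", x$domain_depth,
      " um (", x$n_layers, " layers of ", x$layer_thickness, " um)\n",
      "  D = ", x$diffusion_constant, " um^2/s, Km = ", x$km, " mmHg\n",
      sep = "")
  invisible(x)
}

#' @export
print.krogh_params <- function(x, ...) {
  cat("Krogh perivascular cylinder\n",
      "  capillary pO2: ", x$capillary_po2, " mmHg at r = ",
      x$capillary_radius, " um | outer radius: ", x$outer_radius, " um (",
      x$n_shells, " shells)\n",
      "  CMRO2 = ", x$cmro2, " mmHg/s, D = ", x$diffusion_constant,
      " um^2/s, Km = ", x$km, " mmHg\n", sep = "")
  invisible(x)
}
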