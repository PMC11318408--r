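#' Steady-state oxygen field in a planar brain slice
#'
#' Solves the steady-state reaction-diffusion equation
#' \deqn{D \frac{d^2 p}{dx^2} = M \frac{p}{p + K_m}}
#' on `[0, domain_depth]` with the surface held at the supply pO2 (Dirichlet)
#' and zero diffusive flux at the ptiO2 minimum, discretized on the layer grid
#' in conservative (flux) form. The nonlinearity is handled by
#' quasi-linearized Picard iteration (the Michaelis-Menten term frozen at the
#' previous iterate), whose linearized system is an M-matrix, so every
#' iterate -- and the converged field -- is strictly positive; convergence is
#' declared when the largest node update falls below `tol` and verified on
#' the nonlinear residual.
#'
#' @param params A [slice_model_params()] object.
#' @param cmro2 Oxygen consumption rate at saturation, mmHg/s (>= 0).
#' @param tol Convergence tolerance on the maximum node update, mmHg.
#' @param max_iter Iteration cap before the solver aborts with an error.
#'
#' @return An `oxygen_field` object: a list with `geometry` (`"planar"`),
#'   `positions` (um), `po2` (mmHg, one value per node), and
#'   `boundary_value` (the supply pO2).
#' @examples
#' sp <- slice_model_params(surface_po2 = 150, domain_depth = 160)
#' f <- solve_planar_steady_state(sp, cmro2 = 34.4)
#' min(f$po2)  # core pO2
#' @seealso [solve_cylindrical_steady_state()], [fit_cmro2()]
#' @export
solve_planar_steady_state <- function(params, cmro2, tol = 1e-6,
                                      max_iter = 10000L) {
  stopifnot(inherits(params, "slice_model_params"))
  if (!is.numeric(cmro2) || length(cmro2) != 1L || is.na(cmro2) || cmro2 < 0) {
    stop("`cmro2` must be a non-negative number", call. = FALSE)
  }
  po2 <- .planar_solve_cpp(params$surface_po2, params$n_layers,
                           params$layer_thickness,
                           params$diffusion_constant, params$km, cmro2,
                           tol, as.integer(max_iter))
  oxygen_field("planar",
               positions = seq(0, params$domain_depth,
                               length.out = params$n_layers + 1L),
               po2 = po2, boundary_value = params$surface_po2)
}

#' Steady-state oxygen field in a Krogh cylinder
#'
#' Solves \deqn{\frac{D}{r}\frac{d}{dr}\!\left(r \frac{dp}{dr}\right) =
#' M \frac{p}{p + K_m}} on `[capillary_radius, outer_radius]` with the vessel
#' wall held at capillary pO2 and a closed outer boundary. The flux-form
#' discretization conserves oxygen: the diffusive influx at the vessel wall
#' equals the total consumption over the tissue shells (see
#' [oxygen_flux_balance()]).
#'
#' @param params A [krogh_params()] object.
#' @inheritParams solve_planar_steady_state
#' @return An `oxygen_field` object with `geometry = "cylindrical"`; positions
#'   are radii in um from the cylinder axis.
#' @examples
#' kp <- krogh_params(capillary_po2 = 20, outer_radius = 25, cmro2 = 34.4)
#' f <- solve_cylindrical_steady_state(kp)
#' f$po2[length(f$po2)]  # edge (= minimal) pO2
#' @export
solve_cylindrical_steady_state <- function(params, tol = 1e-6,
                                           max_iter = 10000L) {
  stopifnot(inherits(params, "krogh_params"))
  po2 <- .cyl_solve_cpp(params$capillary_po2, params$capillary_radius,
                        params$outer_radius, params$n_shells,
                        params$diffusion_constant, params$km, params$cmro2,
                        tol, as.integer(max_iter))
  oxygen_field("cylindrical",
               positions = seq(params$capillary_radius, params$outer_radius,
                               length.out = params$n_shells + 1L),
               po2 = po2, boundary_value = params$capillary_po2)
}

oxygen_field <- function(geometry, positions, po2, boundary_value) {
  structure(list(geometry = geometry, positions = positions, po2 = po2,
                 boundary_value = boundary_value),
            class = "oxygen_field")
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat("Oxygen field (", x$geometry, "), ", length(x$po2), " nodes\n",
      "  boundary ", format(x$boundary_value), " mmHg -> minimum ",
      format(round(min(x$po2), 3)), " mmHg at ",
      format(x$positions[which.min(x$po2)]), " um\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.oxygen_field <- function(x, ...) {
  data.frame(position_um = x$positions, po2_mmHg = x$po2)
}

#' Write an oxygen field to CSV or JSON
#'
#' @param field An `oxygen_field`.
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_oxygen_field <- function(field, path) {
  stopifnot(inherits(field, "oxygen_field"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(geometry = field$geometry, boundary_value = field$boundary_value,
           position_um = field$positions, po2_mmHg = field$po2),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  }
  invisible(path)
}

#' Diffusive influx versus total consumption for a cylindrical field
#'
#' Recomputes both sides of the steady-state oxygen balance from a converged
#' cylindrical solution: diffusive influx through the vessel wall (first
#' interior face) and Michaelis-Menten consumption integrated over the tissue
#' shells, both per unit axial length and per radian. At steady state the two
#' agree to discretization round-off.
#'
#' @param field A cylindrical `oxygen_field`.
#' @param params The [krogh_params()] the field was solved with.
#' @return A list with `influx`, `consumption` and `relative_error`.
#' @export
oxygen_flux_balance <- function(field, params) {
  stopifnot(inherits(field, "oxygen_field"),
            field$geometry == "cylindrical",
            inherits(params, "krogh_params"))
  r <- field$positions
  p <- field$po2
  h <- r[2] - r[1]
  influx <- params$diffusion_constant * 0.5 * (r[1] + r[2]) *
    (p[1] - p[2]) / h
  n <- length(r)
  rm <- (r[-1] + r[-n]) / 2
  rp <- c(rm[-1], r[n])
  vol <- (rp^2 - c(rm)^2) / 2
  cons <- sum(vol * params$cmro2 * p[-1] / (p[-1] + params$km))
  list(influx = influx, consumption = cons,
       relative_error = abs(influx - cons) / max(cons, .Machine$double.eps))
}

#' Closed-form zero-order references for the two geometries
#'
#' When consumption is effectively zero-order (pO2 much larger than Km
#' everywhere), the steady states have classical closed forms: the parabolic
#' slice profile `p(x) = p_s - M x (2L - x) / (2D)` and the Krogh-Erlang
#' solution `p(r) = p_c - (M/2D) [R^2 ln(r/r_c) - (r^2 - r_c^2)/2]`. These are
#' the analytic references the numerical solvers are validated against in the
#' nearly-zero-Km limit.
#'
#' @param x,r Positions (um) at which to evaluate.
#' @param surface_po2,capillary_po2 Boundary pO2, mmHg.
#' @param cmro2 Zero-order consumption rate, mmHg/s.
#' @param domain_depth Slice closed-boundary depth L, um.
#' @param capillary_radius,outer_radius Krogh radii r_c and R, um.
#' @param diffusion_constant D, um^2/s.
#' @return pO2 values, mmHg (not clamped; may go negative where the
#'   zero-order assumption breaks down).
#' @examples
#' planar_zero_order(100, surface_po2 = 150, cmro2 = 32, domain_depth = 100)
#' @export
planar_zero_order <- function(x, surface_po2, cmro2, domain_depth,
                              diffusion_constant = 1600) {
  surface_po2 - cmro2 * x * (2 * domain_depth - x) / (2 * diffusion_constant)
}

#' @rdname planar_zero_order
#' @export
krogh_erlang <- function(r, capillary_po2, cmro2, capillary_radius,
                         outer_radius, diffusion_constant = 1600) {
  capillary_po2 - cmro2 / (2 * diffusion_constant) *
    (outer_radius^2 * log(r / capillary_radius) - (r^2 - capillary_radius^2) / 2)
}
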