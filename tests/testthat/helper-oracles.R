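# Independent oracles used to validate the package's solvers and statistics.
# Everything here is deliberately written against different machinery than
# the implementation under test: plain-R fine-grid relaxation, deSolve
# shooting for the two-point boundary-value problems, full 2^n enumeration
# for the signed-rank null, and exhaustive grid search for the scalar fit.

# --- plain-R tridiagonal solve (Thomas algorithm) ---------------------------
thomas_solve_R <- function(sub, diag, sup, rhs) {
  n <- length(diag)
  cp <- numeric(n)
  xp <- numeric(n)
  cp[1] <- sup[1] / diag[1]
  xp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - sub[i] * cp[i - 1]
    cp[i] <- sup[i] / m
    xp[i] <- (rhs[i] - sub[i] * xp[i - 1]) / m
  }
  x <- xp
  for (i in (n - 1):1) x[i] <- xp[i] - cp[i] * x[i + 1]
  x
}

# --- fine-grid planar relaxation oracle -------------------------------------
# Steady state of D p'' = M p/(p+Km), p(0)=ps, p'(L)=0, on a grid `refine`
# times finer than 1 um, by direct fixed-point relaxation in R. Returns a
# function interpolating the oracle solution.
planar_fine_oracle <- function(surface_po2, domain_depth, cmro2, km = 3,
                               D = 1600, refine = 8, tol = 1e-9,
                               max_iter = 50000) {
  h <- 1 / refine
  x <- seq(0, domain_depth, by = h)
  N <- length(x)
  p <- rep(surface_po2, N)
  if (cmro2 > 0) {
    for (it in seq_len(max_iter)) {
      c_i <- cmro2 / (p[-1] + km)
      n <- N - 1
      dg <- -(2 * D / h) - c_i * h
      dg[n] <- -(D / h) - c_i[n] * h / 2   # closed-boundary half cell
      sub <- c(0, rep(D / h, n - 1))
      sup <- c(rep(D / h, n - 1), 0)
      rhs <- c(-D / h * surface_po2, rep(0, n - 1))
      pn <- c(surface_po2, thomas_solve_R(sub, dg, sup, rhs))
      if (max(abs(pn - p)) < tol) { p <- pn; break }
      p <- pn
    }
  }
  stats::approxfun(x, p)
}

# --- deSolve shooting oracles -----------------------------------------------
# Integrate the ODE from the closed boundary (flat start) toward the supply
# boundary and shoot on the unknown closed-boundary value. Suitable when the
# closed-boundary pO2 is not vanishingly small.
planar_shoot_oracle <- function(surface_po2, domain_depth, cmro2, km = 3,
                                D = 1600, n_out = 161) {
  rhs <- function(x, y, parms) {
    list(c(y[2], cmro2 / D * y[1] / (y[1] + km)))
  }
  p_at_surface <- function(p_core) {
    # integrate backward: s = L - x so surface is at s = L
    f <- function(s, y, parms) {
      list(c(-y[2], -(cmro2 / D * y[1] / (y[1] + km))))
    }
    out <- deSolve::lsoda(c(p = p_core, q = 0), c(0, domain_depth), f,
                          parms = NULL, rtol = 1e-10, atol = 1e-12)
    out[nrow(out), "p"]
  }
  core <- stats::uniroot(function(s) p_at_surface(s) - surface_po2,
                         c(1e-8, surface_po2), tol = 1e-12)$root
  f <- function(s, y, parms) {
    list(c(-y[2], -(cmro2 / D * y[1] / (y[1] + km))))
  }
  ss <- seq(0, domain_depth, length.out = n_out)
  out <- deSolve::lsoda(c(p = core, q = 0), ss, f, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  # out is indexed by s = L - x: return on the depth grid
  data.frame(depth = domain_depth - out[, "time"], po2 = out[, "p"])
}

cyl_shoot_oracle <- function(capillary_po2, capillary_radius, outer_radius,
                             cmro2, km = 3, D = 1600, n_out = 101) {
  # p'' + p'/r = (M/D) p/(p+Km); integrate inward from the closed outer edge
  f <- function(r, y, parms) {
    list(c(y[2], cmro2 / D * y[1] / (y[1] + km) - y[2] / r))
  }
  p_at_wall <- function(p_edge) {
    out <- deSolve::lsoda(c(p = p_edge, q = 0),
                          seq(outer_radius, capillary_radius, length.out = 2),
                          f, parms = NULL, rtol = 1e-10, atol = 1e-12)
    out[nrow(out), "p"]
  }
  edge <- stats::uniroot(function(s) p_at_wall(s) - capillary_po2,
                         c(1e-8, capillary_po2), tol = 1e-12)$root
  rr <- seq(outer_radius, capillary_radius, length.out = n_out)
  out <- deSolve::lsoda(c(p = edge, q = 0), rr, f, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  data.frame(radius = out[, "time"], po2 = out[, "p"])
}

# --- exhaustive grid-search CMRO2 fit oracle --------------------------------
grid_search_cmro2 <- function(profile, params, m_grid = seq(0, 500, by = 0.01)) {
  sse <- vapply(m_grid, function(m) {
    f <- solve_planar_steady_state(params, m)
    pred <- stats::approx(f$positions, f$po2, xout = profile$depth)$y
    sum((pred - profile$po2)^2)
  }, numeric(1))
  m_grid[which.min(sse)]
}

# --- full-enumeration signed-rank oracle (n <= ~12) -------------------------
wilcoxon_enum_oracle <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  wdist <- signs %*% r
  lower <- mean(wdist <= w + 1e-12)
  upper <- mean(wdist >= w - 1e-12)
  min(1, 2 * min(lower, upper))
}
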