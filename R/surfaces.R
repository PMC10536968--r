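#' Analytic 1D model potentials
#'
#' A `potential_surface` is an analytic potential-energy function of a
#' single coordinate, built from a cosine series, Gaussian wells and an
#' optional harmonic term.  Periodic surfaces use degrees on
#' \[-period/2, period/2); non-periodic surfaces use an unbounded
#' coordinate (nm or degrees, caller's convention).  Energies are kJ/mol.
#'
#' Surfaces serve as desk-scale stand-ins for the dihedral free-energy
#' landscapes of real solutes: their potential of mean force is available
#' in closed form, so enhanced-sampling and reweighting machinery can be
#' validated against an exact reference.
#'
#' @param cos_amp,cos_mult,cos_phase cosine-series terms
#'   `amp * cos(mult * theta + phase)` with `theta` the coordinate in
#'   radians (after degree conversion).
#' @param g_center,g_depth,g_width Gaussian wells
#'   `depth * exp(-d^2 / (2 width^2))` with `d` the minimum-image
#'   displacement from `center` (same units as the coordinate).
#' @param harm_k,harm_x0 optional harmonic term `k/2 (x - x0)^2`.
#' @param offset constant energy offset (kJ/mol).
#' @param periodic logical; `period` the period in coordinate units.
#' @param mass effective inertia of the coordinate, in
#'   kJ mol^-1 ps^2 per (coordinate unit)^2; sets the dynamical time
#'   scale only, not the equilibrium distribution.
#' @return an object of class `potential_surface`.
#' @export
potential_surface <- function(cos_amp = numeric(), cos_mult = numeric(),
                              cos_phase = numeric(),
                              g_center = numeric(), g_depth = numeric(),
                              g_width = numeric(),
                              harm_k = 0, harm_x0 = 0, offset = 0,
                              periodic = TRUE, period = 360, mass = 1e-4) {
  stopifnot(length(cos_amp) == length(cos_mult),
            length(cos_amp) == length(cos_phase),
            length(g_center) == length(g_depth),
            length(g_center) == length(g_width))
  if (length(g_width) && any(g_width <= 0)) stop("Gaussian widths must be positive")
  s <- structure(list(
    dimension = 1L, periodic = periodic, period = as.numeric(period),
    offset = as.numeric(offset),
    cos_amp = as.numeric(cos_amp), cos_mult = as.numeric(cos_mult),
    cos_phase = as.numeric(cos_phase),
    g_center = as.numeric(g_center), g_depth = as.numeric(g_depth),
    g_width = as.numeric(g_width),
    harm_k = as.numeric(harm_k), harm_x0 = as.numeric(harm_x0),
    mass = as.numeric(mass)), class = "potential_surface")
  v <- surface_energy(s, if (periodic) seq(-period / 2, period / 2, length.out = 7)
                      else harm_x0 + c(-1, 0, 1))
  if (!all(is.finite(v))) stop("surface energy is not finite on its domain")
  s
}

#' Symmetric periodic double well
#'
#' Builds the 1D periodic surface
#' `V(x) = (barrier/2) * (1 + cos(2 pi x * 2 / period))`
#' with two equal-depth minima at +/- period/4 (i.e. +/-90 deg for the
#' default 360 deg period) and barriers of height `barrier` at 0 and
#' period/2.  The analytic potential of mean force of this 1D system
#' equals the surface itself up to an additive constant.
#'
#' @param barrier barrier height in kJ/mol (> 0).
#' @param period period in degrees.
#' @param mass effective inertia (see [potential_surface()]).
#' @return a `potential_surface`.
#' @examples
#' dw <- make_double_well(10)
#' surface_energy(dw, c(-90, 0, 90))  # 0, 10, 0
#' @export
make_double_well <- function(barrier, period = 360, mass = 1e-4) {
  if (!is.numeric(barrier) || length(barrier) != 1 || barrier <= 0)
    stop("barrier must be a positive scalar (kJ/mol)")
  # coordinate in degrees; multiplicity 2 relative to the full period
  mult <- 2 * 360 / period
  potential_surface(cos_amp = barrier / 2, cos_mult = mult, cos_phase = 0,
                    offset = barrier / 2, periodic = TRUE, period = period,
                    mass = mass)
}

#' Harmonic well (non-periodic)
#'
#' @param k_spring force constant, kJ/mol per (coordinate unit)^2.
#' @param x0 minimum position.
#' @inheritParams make_double_well
#' @return a `potential_surface` with `periodic = FALSE`.
#' @export
make_harmonic_well <- function(k_spring, x0 = 0, mass = 1e-4) {
  if (k_spring <= 0) stop("k_spring must be positive")
  potential_surface(harm_k = k_spring, harm_x0 = x0,
                    periodic = FALSE, period = Inf, mass = mass)
}

mi_dist <- function(s, d) {
  if (!s$periodic) return(d)
  wrap_periodic(d, s$period)
}

#' Surface energy and gradient
#'
#' `surface_energy()` evaluates the analytic potential; `surface_gradient()`
#' its analytic derivative dV/dx (so the force is the negative of it).
#' Both are vectorised over `x`.
#'
#' @param surface a `potential_surface`.
#' @param x coordinate values (degrees for periodic surfaces).
#' @return numeric vector, kJ/mol (energy) or kJ/mol per unit (gradient).
#' @export
surface_energy <- function(surface, x) {
  th <- x * pi / 180
  v <- rep(surface$offset, length(x))
  for (i in seq_along(surface$cos_amp))
    v <- v + surface$cos_amp[i] * cos(surface$cos_mult[i] * th + surface$cos_phase[i])
  for (i in seq_along(surface$g_center)) {
    d <- mi_dist(surface, x - surface$g_center[i])
    v <- v + surface$g_depth[i] * exp(-0.5 * d^2 / surface$g_width[i]^2)
  }
  if (surface$harm_k != 0)
    v <- v + 0.5 * surface$harm_k * (x - surface$harm_x0)^2
  v
}

#' @rdname surface_energy
#' @export
surface_gradient <- function(surface, x) {
  th <- x * pi / 180
  g <- rep(0, length(x))
  for (i in seq_along(surface$cos_amp))
    g <- g - surface$cos_amp[i] * surface$cos_mult[i] *
      sin(surface$cos_mult[i] * th + surface$cos_phase[i]) * pi / 180
  for (i in seq_along(surface$g_center)) {
    d <- mi_dist(surface, x - surface$g_center[i])
    w2 <- surface$g_width[i]^2
    g <- g - surface$g_depth[i] * exp(-0.5 * d^2 / w2) * d / w2
  }
  if (surface$harm_k != 0)
    g <- g + surface$harm_k * (x - surface$harm_x0)
  g
}

#' Analytic potential of mean force of a 1D surface
#'
#' For a 1D system the PMF along the coordinate is the potential itself,
#' anchored so that its minimum over the evaluation grid is zero.
#'
#' @param surface a `potential_surface`.
#' @param x coordinates at which to evaluate the PMF.
#' @return numeric vector of PMF values (kJ/mol), min 0.
#' @export
surface_pmf <- function(surface, x) {
  v <- surface_energy(surface, x)
  v - min(v)
}

#' Boltzmann population of a coordinate interval
#'
#' Numerical quadrature of `exp(-V(x)/kB T)` over `[lo, hi]`, normalised
#' by the integral over the full period (periodic surfaces) or over
#' `+/- 10` thermal standard deviations (harmonic surfaces).  Used as an
#' independent reference for sampled populations.
#'
#' @param surface a `potential_surface`.
#' @param lo,hi interval bounds (coordinate units).
#' @param temperature K.
#' @return probability in \[0, 1\].
#' @export
boltzmann_population <- function(surface, lo, hi, temperature = 300) {
  beta <- 1 / (kB * temperature)
  f <- function(x) exp(-beta * surface_energy(surface, x))
  if (surface$periodic) {
    dom <- c(-surface$period / 2, surface$period / 2)
  } else {
    sdx <- sqrt(1 / (beta * max(surface$harm_k, 1e-12)))
    dom <- surface$harm_x0 + c(-10, 10) * sdx
  }
  z <- integrate(f, dom[1], dom[2], rel.tol = 1e-10)$value
  integrate(f, lo, hi, rel.tol = 1e-10)$value / z
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("<potential_surface> 1D,",
      if (x$periodic) sprintf("periodic (period %g deg),", x$period) else "non-periodic,",
      length(x$cos_amp), "cosine term(s),",
      length(x$g_center), "Gaussian well(s),",
      if (x$harm_k != 0) sprintf("harmonic k=%g,", x$harm_k) else "",
      sprintf("mass %g\n", x$mass))
  invisible(x)
}
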