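#' Casson blood model
#'
#' Blood is modelled as an incompressible Casson fluid: a yield-stress,
#' shear-thinning material whose effective viscosity is
#' \deqn{\mu_{eff}(\dot\gamma) = \left(\sqrt{\eta_c} +
#'   \sqrt{\tau_c/\dot\gamma}\right)^2,}
#' with plastic viscosity \eqn{\eta_c} and yield stress \eqn{\tau_c}. Below a
#' configurable shear-rate floor the shear rate is clamped (standard
#' yield-stress regularization) so plug regions do not divide by zero.
#' Defaults are the whole-blood values used throughout: density 1060 kg/m3,
#' \eqn{\eta_c} = 0.0035 Pa s, \eqn{\tau_c} = 0.004 Pa.
#'
#' @param density Blood density, kg/m3.
#' @param eta_c Casson plastic viscosity, Pa s.
#' @param tau_c Casson yield stress, Pa (0 gives a Newtonian fluid).
#' @param gamma_floor Minimum shear rate used when evaluating the viscosity,
#'   1/s.
#' @return An object of class `casson_fluid`.
#' @export
#' @examples
#' blood <- casson_fluid()
#' effective_viscosity(blood, c(1, 10, 1e4))
casson_fluid <- function(density = 1060, eta_c = 0.0035, tau_c = 0.004,
                         gamma_floor = 1e-6) {
  check_number(density, "density", min = 0, strict_min = TRUE)
  check_number(eta_c, "eta_c", min = 0, strict_min = TRUE)
  check_number(tau_c, "tau_c", min = 0)
  check_number(gamma_floor, "gamma_floor", min = 0, strict_min = TRUE)
  structure(list(density = density, eta_c = eta_c, tau_c = tau_c,
                 gamma_floor = gamma_floor),
            class = "casson_fluid")
}

#' @export
print.casson_fluid <- function(x, ...) {
  cat(sprintf(
    "<casson_fluid> rho = %g kg/m3, eta_c = %g Pa.s, tau_c = %g Pa (floor %g 1/s)\n",
    x$density, x$eta_c, x$tau_c, x$gamma_floor))
  invisible(x)
}

#' Casson effective viscosity
#'
#' Evaluates the Casson effective viscosity at the given shear rates. Shear
#' rates below the fluid's `gamma_floor` are clamped to the floor. The result
#' is monotone non-increasing in shear rate (shear thinning), bounded below by
#' `eta_c`, and exactly `eta_c` for a Newtonian fluid (`tau_c = 0`).
#'
#' @param fluid A [casson_fluid()].
#' @param shear_rate Shear rate(s), 1/s; must be finite and non-negative.
#' @return Effective viscosity, Pa s (vectorised over `shear_rate`).
#' @export
effective_viscosity <- function(fluid, shear_rate) {
  stopifnot(inherits(fluid, "casson_fluid"))
  if (!is.numeric(shear_rate) || length(shear_rate) == 0 ||
      any(!is.finite(shear_rate)) || any(shear_rate < 0)) {
    abort("`shear_rate` must be finite and non-negative.",
          class = "cowflow_invalid_input")
  }
  g <- pmax(shear_rate, fluid$gamma_floor)
  (sqrt(fluid$eta_c) + sqrt(fluid$tau_c / g))^2
}

# dimensionless Casson flow-rate factor f(xi), xi = tau_c / tau_w in [0, 1]:
# Q = pi R^4 G / (8 eta_c) * f(xi)
casson_flow_factor <- function(xi) {
  1 - (16 / 7) * sqrt(xi) + (4 / 3) * xi - (1 / 21) * xi^4
}

# d/dG [G f(xi(G))] = f(xi) - xi f'(xi)   (since dxi/dG = -xi/G)
casson_flow_factor_dG <- function(xi) {
  fp <- -(8 / 7) / sqrt(xi) + 4 / 3 - (4 / 21) * xi^3
  casson_flow_factor(xi) - xi * fp
}

#' Steady Casson flow in a rigid circular pipe
#'
#' Closed-form solution for fully developed, steady Casson flow driven by a
#' constant axial pressure gradient: the classical flow-rate expression
#' \eqn{Q = \pi R^4 G/(8\eta_c)\,[1 - (16/7)\sqrt{\xi} + (4/3)\xi -
#' \xi^4/21]} with \eqn{\xi = \tau_c/\tau_w} and wall shear stress
#' \eqn{\tau_w = GR/2}. At or below yield (\eqn{\tau_w \le \tau_c}) the fluid
#' does not move. This is the verification oracle for the finite-volume solver
#' and the constitutive element of the network solver.
#'
#' @param fluid A [casson_fluid()].
#' @param radius Pipe radius, m.
#' @param pressure_gradient Driving pressure gradient \eqn{G = -dp/dz}, Pa/m;
#'   non-negative (vectorised).
#' @return A tibble with one row per gradient: `flow_rate` (m3/s),
#'   `peak_velocity` and `mean_velocity` (m/s), `plug_radius` (m),
#'   `wall_shear_stress` (Pa).
#' @export
#' @examples
#' casson_pipe_flow(casson_fluid(), radius = 2e-3, pressure_gradient = 1000)
casson_pipe_flow <- function(fluid, radius, pressure_gradient) {
  stopifnot(inherits(fluid, "casson_fluid"))
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  if (any(!is.finite(pressure_gradient)) || any(pressure_gradient < 0)) {
    abort("`pressure_gradient` must be finite and non-negative.",
          class = "cowflow_invalid_input")
  }
  G <- pressure_gradient
  R <- radius
  tau_w <- G * R / 2
  plug <- ifelse(G > 0, pmin(2 * fluid$tau_c / G, R), R)
  flowing <- tau_w > fluid$tau_c
  xi <- ifelse(flowing, fluid$tau_c / tau_w, 1)
  Q <- ifelse(flowing,
              pi * R^4 * G / (8 * fluid$eta_c) * casson_flow_factor(xi),
              0)
  upk <- vapply(seq_along(G), function(k) {
    if (!flowing[k]) return(0)
    casson_plug_velocity(fluid, R, G[k])
  }, numeric(1))
  tibble(flow_rate = Q,
         peak_velocity = upk,
         mean_velocity = Q / (pi * R^2),
         plug_radius = plug,
         wall_shear_stress = tau_w)
}

# scalar fast path used by the solvers (no tibble construction)
casson_flow_scalar <- function(fluid, R, G) {
  tau_w <- G * R / 2
  if (tau_w <= fluid$tau_c) return(0)
  xi <- fluid$tau_c / tau_w
  pi * R^4 * G / (8 * fluid$eta_c) * casson_flow_factor(xi)
}

# centerline (plug) velocity of the analytic Casson profile
casson_plug_velocity <- function(fluid, R, G) {
  rp <- min(2 * fluid$tau_c / G, R)
  (1 / fluid$eta_c) * (
    G * (R^2 - rp^2) / 4 -
      (4 / 3) * sqrt(G * fluid$tau_c / 2) * (R^1.5 - rp^1.5) +
      fluid$tau_c * (R - rp))
}

#' Analytic Casson velocity profile
#'
#' Piecewise velocity profile of developed Casson pipe flow: a flat plug for
#' \eqn{r \le r_p = 2\tau_c/G} and, outside the plug, the integral of the
#' Casson shear-rate relation from the wall inward. Continuous, continuously
#' matched at the plug boundary, and zero at the wall (no slip).
#'
#' @inheritParams casson_pipe_flow
#' @param r Radial position(s), m, in `[0, radius]` (vectorised).
#' @return Axial velocity, m/s.
#' @export
casson_velocity_profile <- function(fluid, radius, pressure_gradient, r) {
  stopifnot(inherits(fluid, "casson_fluid"))
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  check_number(pressure_gradient, "pressure_gradient", min = 0)
  if (any(!is.finite(r)) || any(r < 0) || any(r > radius * (1 + 1e-12))) {
    abort("`r` must lie in [0, radius].", class = "cowflow_invalid_input")
  }
  G <- pressure_gradient
  R <- radius
  if (G * R / 2 <= fluid$tau_c) return(rep(0, length(r)))
  rp <- min(2 * fluid$tau_c / G, R)
  u_of <- function(rr) {
    (1 / fluid$eta_c) * (
      G * (R^2 - rr^2) / 4 -
        (4 / 3) * sqrt(G * fluid$tau_c / 2) * (R^1.5 - rr^1.5) +
        fluid$tau_c * (R - rr))
  }
  ifelse(r <= rp, u_of(rp), u_of(pmin(r, R)))
}

#' Peak-to-mean velocity ratio of Casson pipe flow
#'
#' Ratio of cross-sectional mean to centreline (plug) velocity. Used to
#' convert a Doppler envelope peak velocity into volumetric flow at the
#' inlets. Equals exactly 0.5 in the Newtonian limit and tends to 1 as the
#' wall shear stress approaches the yield stress (flat plug).
#'
#' @inheritParams casson_pipe_flow
#' @return Dimensionless ratio mean/peak in (0.5, 1).
#' @export
peak_to_mean_ratio <- function(fluid, radius, pressure_gradient) {
  stopifnot(inherits(fluid, "casson_fluid"))
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  check_number(pressure_gradient, "pressure_gradient", min = 0)
  if (pressure_gradient * radius / 2 <= fluid$tau_c) {
    abort("Flow is at or below yield: wall shear stress <= tau_c.",
          class = "cowflow_below_yield")
  }
  res <- casson_pipe_flow(fluid, radius, pressure_gradient)
  res$mean_velocity / res$peak_velocity
}

#' Invert the Casson pipe law
#'
#' `invert_flow_to_gradient()` returns the pressure gradient G that produces a
#' given volumetric flow rate; `invert_peak_to_gradient()` the gradient that
#' produces a given centreline (Doppler peak) velocity. Both use bracketed
#' bisection in log-gradient: Q(G) and u_peak(G) are strictly increasing and
#' continuous above yield, so bracketing is globally convergent; iteration
#' stops at relative tolerance 1e-10 (refined beyond it by the final
#' interval). For zero flow the conventional yield gradient `2 tau_c / R` is
#' returned.
#'
#' @inheritParams casson_pipe_flow
#' @param flow_rate Target flow rate, m3/s (non-negative).
#' @param peak_velocity Target centreline velocity, m/s (non-negative).
#' @return Pressure gradient, Pa/m.
#' @export
#' @examples
#' fl <- casson_fluid()
#' G <- invert_flow_to_gradient(fl, 2.5e-3, flow_rate = 4e-6) # 4 mL/s
#' casson_pipe_flow(fl, 2.5e-3, G)$flow_rate
invert_flow_to_gradient <- function(fluid, radius, flow_rate) {
  stopifnot(inherits(fluid, "casson_fluid"))
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  check_number(flow_rate, "flow_rate", min = 0)
  if (flow_rate == 0) return(2 * fluid$tau_c / radius)
  if (fluid$tau_c == 0) {
    return(8 * fluid$eta_c * flow_rate / (pi * radius^4))
  }
  casson_bisect(function(G) casson_flow_scalar(fluid, radius, G),
                target = flow_rate, fluid = fluid, radius = radius)
}

#' @rdname invert_flow_to_gradient
#' @export
invert_peak_to_gradient <- function(fluid, radius, peak_velocity) {
  stopifnot(inherits(fluid, "casson_fluid"))
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  check_number(peak_velocity, "peak_velocity", min = 0)
  if (peak_velocity == 0) return(2 * fluid$tau_c / radius)
  if (fluid$tau_c == 0) {
    return(4 * fluid$eta_c * peak_velocity / radius^2)
  }
  casson_bisect(function(G) casson_plug_velocity(fluid, radius, G),
                target = peak_velocity, fluid = fluid, radius = radius)
}

# monotone bracketed bisection in log G, relative tolerance 1e-10
casson_bisect <- function(fn, target, fluid, radius, rel_tol = 1e-10) {
  G_yield <- 2 * fluid$tau_c / radius
  lo <- G_yield * (1 + 1e-14)
  hi <- max(G_yield * 2, 8 * fluid$eta_c * target / (pi * radius^4),
            4 * fluid$eta_c * target / radius^2, 1e-6)
  for (k in 1:200) {
    if (fn(hi) >= target) break
    hi <- hi * 4
  }
  llo <- log(lo); lhi <- log(hi)
  for (k in 1:200) {
    mid <- (llo + lhi) / 2
    if (fn(exp(mid)) < target) llo <- mid else lhi <- mid
    if ((lhi - llo) < rel_tol * 1e-2) break
  }
  exp((llo + lhi) / 2)
}
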