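#' Axisymmetric finite-volume grid for a single vessel segment
#'
#' Uniform staggered grid in cylindrical (r, z) coordinates covering one
#' vessel segment. The radius profile may be constant, linearly tapered, or a
#' cosine stenosis (radius reduced by `stenosis_severity` at the throat over
#' a window of `stenosis_extent` of the length, centred at mid-length).
#' Non-constant profiles are represented by blocked (solid) cells on the
#' uniform grid; quantitative verification against the analytic solution is
#' done on straight tubes.
#'
#' @param n_radial Radial cell count (>= 8).
#' @param n_axial Axial cell count (>= 16).
#' @param length Segment length, m.
#' @param radius Proximal radius, m.
#' @param taper_ratio Distal/proximal radius ratio (1 = straight).
#' @param stenosis_severity Fractional radius reduction at the throat in
#'   `[0, 0.9]` (0 = none).
#' @param stenosis_extent Axial extent of the stenosis as a fraction of the
#'   length.
#' @return An object of class `cow_grid`.
#' @export
axisymmetric_grid <- function(n_radial, n_axial, length, radius,
                              taper_ratio = 1, stenosis_severity = 0,
                              stenosis_extent = 0.5) {
  if (n_radial < 8 || n_axial < 16) {
    abort("Grid must have n_radial >= 8 and n_axial >= 16.",
          class = "cowflow_invalid_input")
  }
  check_number(length, "length", min = 0, strict_min = TRUE)
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  check_number(taper_ratio, "taper_ratio", min = 0.2, max = 1.5)
  check_number(stenosis_severity, "stenosis_severity", min = 0, max = 0.9)
  radius_of <- function(z) {
    base <- radius * (1 + (taper_ratio - 1) * z / length)
    if (stenosis_severity > 0) {
      w <- stenosis_extent * length
      inwin <- abs(z - length / 2) < w / 2
      red <- ifelse(inwin,
                    (stenosis_severity / 2) *
                      (1 + cos(2 * pi * (z - length / 2) / w)),
                    0)
      base <- base * (1 - red)
    }
    base
  }
  structure(list(n_radial = as.integer(n_radial),
                 n_axial = as.integer(n_axial),
                 length = length, radius = radius,
                 taper_ratio = taper_ratio,
                 stenosis_severity = stenosis_severity,
                 stenosis_extent = stenosis_extent,
                 radius_of = radius_of,
                 r_max = max(radius, radius * taper_ratio)),
            class = "cow_grid")
}

#' Solver settings for the pressure-correction scheme
#'
#' Controls of the steady SIMPLE-family iteration: an optional implicit
#' momentum predictor at the start of each outer iteration (without it a
#' single explicit Jacobi sweep is used), one or more pressure-correction
#' corrector loops per outer iteration for stability, under-relaxation of
#' velocity and pressure (the pseudo-time analogue of large time steps), a
#' Picard-lagged viscosity update with its own relaxation, and normalized
#' mass/momentum residual tolerances.
#'
#' @param momentum_predictor Solve the momentum equations implicitly each
#'   outer iteration?
#' @param n_corrector_loops Number of pressure-correction loops (>= 1).
#' @param under_relaxation_velocity,under_relaxation_pressure Relaxation
#'   factors in (0, 1].
#' @param viscosity_relaxation Relaxation of the shear-dependent viscosity
#'   update.
#' @param residual_tolerance Normalized mass and momentum residual target.
#' @param max_outer_iterations Outer iteration cap.
#' @return A list of class `cow_solver_settings`.
#' @export
solver_settings <- function(momentum_predictor = TRUE,
                            n_corrector_loops = 2,
                            under_relaxation_velocity = 0.7,
                            under_relaxation_pressure = 0.3,
                            viscosity_relaxation = 0.7,
                            residual_tolerance = 1e-6,
                            max_outer_iterations = 600) {
  if (n_corrector_loops < 1) {
    abort("`n_corrector_loops` must be >= 1.", class = "cowflow_invalid_input")
  }
  check_number(under_relaxation_velocity, "under_relaxation_velocity",
               min = 0, max = 1, strict_min = TRUE)
  check_number(under_relaxation_pressure, "under_relaxation_pressure",
               min = 0, max = 1, strict_min = TRUE)
  check_number(residual_tolerance, "residual_tolerance", min = 0,
               strict_min = TRUE)
  structure(list(momentum_predictor = isTRUE(momentum_predictor),
                 n_corrector_loops = as.integer(n_corrector_loops),
                 under_relaxation_velocity = under_relaxation_velocity,
                 under_relaxation_pressure = under_relaxation_pressure,
                 viscosity_relaxation = viscosity_relaxation,
                 residual_tolerance = residual_tolerance,
                 max_outer_iterations = as.integer(max_outer_iterations)),
            class = "cow_solver_settings")
}

#' Inlet specification for the segment solver
#'
#' @param peak_velocity Centreline velocity at the inlet, m/s.
#' @param profile "casson" imposes the analytic developed Casson profile with
#'   that peak; "flat" imposes a uniform velocity equal to `peak_velocity`.
#' @return A list of class `cow_inlet`.
#' @export
inlet_spec <- function(peak_velocity, profile = c("casson", "flat")) {
  check_number(peak_velocity, "peak_velocity", min = 0)
  structure(list(peak_velocity = peak_velocity,
                 profile = match.arg(profile)),
            class = "cow_inlet")
}

#' Solve steady Casson flow in one vessel segment
#'
#' Finite-volume solution of the steady incompressible momentum and
#' continuity equations with the Casson effective viscosity evaluated per
#' cell from the local shear rate. Velocity inlet, pressure outlet, rigid
#' no-slip wall. The steady state is reached by iterating a SIMPLE-family
#' pressure-correction loop (optional implicit momentum predictor, one or
#' more corrector loops, first-order upwind convection, central diffusion)
#' until the normalized mass and momentum residuals fall below tolerance.
#' Global mass conservation is enforced to machine precision every iteration
#' by scaling the outlet velocity to the prescribed inlet flow.
#'
#' @param grid An [axisymmetric_grid()].
#' @param fluid A [casson_fluid()].
#' @param inlet An [inlet_spec()] (or a single number, taken as a Casson
#'   profile peak velocity in m/s).
#' @param outlet_pressure Outlet pressure, Pa.
#' @param settings A [solver_settings()].
#' @return A `cow_field_solution`: matrices `u` (axial velocity on axial
#'   faces, `n_radial` x `n_axial`+1), `v`, `p`, `mu`, `shear_rate`; a
#'   `residual_history` tibble; `converged`; mass-conservation summary.
#' @export
solve_segment <- function(grid, fluid, inlet, outlet_pressure = 0,
                          settings = solver_settings()) {
  stopifnot(inherits(grid, "cow_grid"), inherits(fluid, "casson_fluid"))
  if (is.numeric(inlet)) inlet <- inlet_spec(inlet)
  stopifnot(inherits(inlet, "cow_inlet"))
  check_number(outlet_pressure, "outlet_pressure")

  nr <- grid$n_radial; nz <- grid$n_axial
  Rmax <- grid$r_max
  dr <- Rmax / nr; dz <- grid$length / nz
  r_c <- (seq_len(nr) - 0.5) * dr          # cell-centre radii
  r_f <- seq_len(nr) * dr                  # radial face radii (1..nr); axis=0
  z_c <- (seq_len(nz) - 0.5) * dz
  rho <- fluid$density
  Az <- 2 * pi * r_c * dr                  # axial-flow face area per row
  An <- 2 * pi * r_f * dz                  # radial-flow face area at r_f[i]

  Rz <- grid$radius_of(z_c)
  fluid_cell <- outer(r_c, Rz, function(r, R) r <= R + 1e-12)  # nr x nz

  # inlet profile at cell-centre radii (clipped to the local lumen)
  R_in <- grid$radius_of(0)
  u_in <- rep(0, nr)
  if (inlet$peak_velocity > 0) {
    if (inlet$profile == "casson") {
      G_in <- invert_peak_to_gradient(fluid, R_in, inlet$peak_velocity)
      u_in <- ifelse(r_c <= R_in,
                     casson_velocity_profile(fluid, R_in, G_in,
                                             pmin(r_c, R_in)), 0)
    } else {
      u_in <- ifelse(r_c <= R_in, inlet$peak_velocity, 0)
    }
  }
  Q_in <- sum(Az * u_in)

  empty_hist <- tibble(iteration = integer(0), mass_residual = numeric(0),
                       momentum_residual = numeric(0))
  if (Q_in <= 0) {
    # no flow: exact solution is zero velocity, uniform outlet pressure
    sol <- list(u = matrix(0, nr, nz + 1), v = matrix(0, nr + 1, nz),
                p = matrix(outlet_pressure, nr, nz),
                mu = matrix(effective_viscosity(fluid, fluid$gamma_floor),
                            nr, nz),
                shear_rate = matrix(0, nr, nz),
                residual_history = empty_hist, converged = TRUE,
                iterations = 0L, q_in = 0, q_out = 0, mass_error = 0,
                grid = grid, fluid = fluid, inlet = inlet,
                outlet_pressure = outlet_pressure)
    return(structure(sol, class = "cow_field_solution"))
  }

  # initial fields: developed flow everywhere, linear pressure
  G0 <- invert_flow_to_gradient(fluid, R_in, Q_in)
  u <- matrix(u_in, nr, nz + 1)
  v <- matrix(0, nr + 1, nz)
  p <- matrix(rep(outlet_pressure + G0 * (grid$length - z_c), each = nr),
              nr, nz)
  mu <- matrix(effective_viscosity(fluid, pmax(abs(G0 * r_c / 2) / 0.0035, 1)),
               nr, nz)  # rough start; replaced by the first Picard update
  mu <- update_viscosity(u, v, mu, fluid, r_c, dr, dz, relax = 1)

  alpha_u <- settings$under_relaxation_velocity
  alpha_p <- settings$under_relaxation_pressure
  tol <- settings$residual_tolerance

  solid_u <- matrix(FALSE, nr, nz - 1)
  for (j in seq_len(nz - 1)) {
    solid_u[, j] <- !(fluid_cell[, j] & fluid_cell[, j + 1])
  }
  solid_p <- !fluid_cell
  solid_v <- !(fluid_cell[seq_len(nr - 1), , drop = FALSE] &
                 fluid_cell[2:nr, , drop = FALSE])

  hist_it <- integer(0); hist_mass <- numeric(0); hist_mom <- numeric(0)
  converged <- FALSE
  mom_res <- Inf; mass_res <- Inf

  scale_outlet <- function(u) {
    u[, nz + 1] <- u[, nz]
    q <- sum(Az * u[, nz + 1])
    if (q > 1e-300) u[, nz + 1] <- u[, nz + 1] * (Q_in / q)
    else u[, nz + 1] <- u_in
    u
  }
  u <- scale_outlet(u)

  for (it in seq_len(settings$max_outer_iterations)) {
    asm <- assemble_u(u, v, p, mu, rho, nr, nz, dr, dz, r_c, r_f, Az, An,
                      u_in, solid_u, fluid_cell)
    mom_res <- asm$residual
    if (settings$momentum_predictor) {
      # implicit under-relaxation: relaxed diagonal, compensating source
      rhs <- asm$b + (1 - alpha_u) / alpha_u * asm$ap0 * asm$u_cur
      sysu <- Matrix::sparseMatrix(i = asm$ti, j = asm$tj, x = asm$tx,
                                   dims = c(asm$n, asm$n))
      Matrix::diag(sysu) <- asm$ap0 / alpha_u
      un <- as.numeric(Matrix::solve(sysu, rhs))
      u[, 2:nz] <- matrix(un, nr, nz - 1)
    } else {
      # single explicit Jacobi sweep with the assembled coefficients
      un <- (asm$offsum + asm$b) / (asm$ap0 / alpha_u) +
        (1 - alpha_u) * asm$u_cur
      u[, 2:nz] <- matrix(un, nr, nz - 1)
    }
    u[, 2:nz][solid_u] <- 0
    u <- scale_outlet(u)

    asv <- assemble_v(u, v, p, mu, rho, nr, nz, dr, dz, r_c, r_f, Az,
                      fluid_cell)
    if (nr > 1) {
      sysv <- Matrix::sparseMatrix(i = asv$ti, j = asv$tj, x = asv$tx,
                                   dims = c(asv$n, asv$n))
      Matrix::diag(sysv) <- asv$ap0 / alpha_u
      rhsv <- asv$b + (1 - alpha_u) / alpha_u * asv$ap0 * asv$v_cur
      vn <- as.numeric(Matrix::solve(sysv, rhsv))
      v[2:nr, ] <- matrix(vn, nr - 1, nz)
    }

    # pressure correction (one or more corrector loops)
    d_u <- Az / (matrix(asm$ap0, nr, nz - 1) / alpha_u)
    d_u[solid_u] <- 0
    d_v <- matrix(0, nr - 1, nz)
    if (nr > 1) {
      d_v <- (2 * pi * r_f[seq_len(nr - 1)] * dz) /
        (matrix(asv$ap0, nr - 1, nz) / alpha_u)
      d_v[solid_v] <- 0
    }
    for (corr in seq_len(settings$n_corrector_loops)) {
      pc <- pressure_correction(u, v, rho, nr, nz, dz, Az, r_f, d_u, d_v,
                                solid_p)
      if (corr == 1) mass_res <- pc$mass_residual / (rho * Q_in)
      p <- p + alpha_p * pc$pp
      u[, 2:nz] <- u[, 2:nz] + d_u * (pc$pp[, 1:(nz - 1)] - pc$pp[, 2:nz])
      u[, 2:nz][solid_u] <- 0
      if (nr > 1) {
        v[2:nr, ] <- v[2:nr, ] + d_v * (pc$pp[1:(nr - 1), ] - pc$pp[2:nr, ])
      }
      u <- scale_outlet(u)
    }

    # anchor the pressure level at the outlet boundary
    p_face_out <- p[, nz] + 0.5 * (p[, nz] - p[, nz - 1])
    p <- p + (outlet_pressure - sum(Az * p_face_out) / sum(Az))

    mu <- update_viscosity(u, v, mu, fluid, r_c, dr, dz,
                           relax = settings$viscosity_relaxation)

    hist_it <- c(hist_it, it); hist_mass <- c(hist_mass, mass_res)
    hist_mom <- c(hist_mom, mom_res)
    if (mass_res <= tol && mom_res <= tol) { converged <- TRUE; break }
  }

  hist <- tibble(iteration = hist_it, mass_residual = hist_mass,
                 momentum_residual = hist_mom)
  if (!converged) {
    stalled <- fluid$tau_c > 0 && max(abs(u)) < 1e-10 * inlet$peak_velocity
    abort(sprintf(
      "Segment solver did not converge in %d iterations (mass %.2e, momentum %.2e).%s",
      settings$max_outer_iterations, mass_res, mom_res,
      if (stalled) " Flow appears yield-dominated (stalled plug)." else ""),
      class = if (stalled) c("cowflow_yield_stall", "cowflow_nonconvergence")
              else "cowflow_nonconvergence",
      residual_history = hist)
  }

  q_out <- sum(Az * u[, nz + 1])
  gam <- attr(mu, "shear_rate")
  sol <- list(u = u, v = v, p = p, mu = mu,
              shear_rate = gam,
              residual_history = hist, converged = converged,
              iterations = length(hist_it),
              q_in = Q_in, q_out = q_out,
              mass_error = abs(Q_in - q_out) / Q_in,
              grid = grid, fluid = fluid, inlet = inlet,
              outlet_pressure = outlet_pressure)
  structure(sol, class = "cow_field_solution")
}

#' @export
print.cow_field_solution <- function(x, ...) {
  cat(sprintf(
    "<cow_field_solution> %dx%d grid, %d iterations, converged: %s, |dQ|/Q = %.1e\n",
    x$grid$n_radial, x$grid$n_axial, x$iterations, x$converged, x$mass_error))
  invisible(x)
}

# --- assembly kernels (vectorised over the whole grid) -----------------------

assemble_u <- function(u, v, p, mu, rho, nr, nz, dr, dz, r_c, r_f, Az, An,
                       u_in, solid_u, fluid_cell) {
  jj <- seq_len(nz - 1)                    # interior axial faces
  n <- nr * (nz - 1)
  idx <- matrix(seq_len(n), nr, nz - 1)

  muW <- mu[, jj, drop = FALSE]; muE <- mu[, jj + 1, drop = FALSE]
  AzM <- matrix(Az, nr, nz - 1)

  Fe <- rho * 0.5 * (u[, jj + 1] + u[, jj + 2]) * AzM
  Fw <- rho * 0.5 * (u[, jj] + u[, jj + 1]) * AzM
  vN <- 0.5 * (v[2:(nr + 1), jj, drop = FALSE] +
                 v[2:(nr + 1), jj + 1, drop = FALSE])
  vS <- 0.5 * (v[1:nr, jj, drop = FALSE] + v[1:nr, jj + 1, drop = FALSE])
  AnM <- matrix(An, nr, nz - 1)
  AsM <- matrix(c(0, An[seq_len(nr - 1)]), nr, nz - 1)
  Fn <- rho * vN * AnM
  Fs <- rho * vS * AsM

  De <- muE * AzM / dz
  Dw <- muW * AzM / dz
  # radial face viscosities (4-cell corner averages); wall row uses half-cell
  muN <- matrix(0, nr, nz - 1)
  if (nr > 1) {
    muN[1:(nr - 1), ] <- 0.25 * (mu[1:(nr - 1), jj] + mu[1:(nr - 1), jj + 1] +
                                   mu[2:nr, jj] + mu[2:nr, jj + 1])
  }
  muN[nr, ] <- 0.5 * (mu[nr, jj] + mu[nr, jj + 1])
  muS <- matrix(0, nr, nz - 1)
  if (nr > 1) {
    muS[2:nr, ] <- muN[1:(nr - 1), ]
  }
  Dn <- muN * AnM / dr
  Dn[nr, ] <- muN[nr, ] * AnM[nr, ] / (dr / 2)   # no-slip wall, half distance
  Fn[nr, ] <- 0
  Ds <- muS * AsM / dr                            # zero on the axis row

  # staircase walls: faces whose northern cell pair is solid act as walls
  if (any(!fluid_cell)) {
    northsolid <- matrix(FALSE, nr, nz - 1)
    if (nr > 1) {
      northsolid[1:(nr - 1), ] <- !(fluid_cell[2:nr, jj] &
                                      fluid_cell[2:nr, jj + 1])
    }
    wallrow <- northsolid & !solid_u
    Dn[wallrow] <- (muN * AnM / (dr / 2))[wallrow]
    Fn[wallrow] <- 0
  }

  aE <- De + pmax(-Fe, 0)
  aW <- Dw + pmax(Fw, 0)
  aN <- Dn + pmax(-Fn, 0)
  aS <- Ds + pmax(Fs, 0)
  ap0 <- aE + aW + aN + aS + (Fe - Fw + Fn - Fs)

  # transpose-stress contribution, explicit (vanishes in developed flow)
  t1 <- mu * (u[, 2:(nz + 1)] - u[, 1:nz]) / dz          # mu du/dz at centres
  st1 <- (t1[, jj + 1] - t1[, jj]) / dz * matrix(r_c * dr * 2 * pi * dz,
                                                 nr, nz - 1)
  t2 <- matrix(0, nr + 1, nz - 1)                         # r mu dv/dz at corners
  if (nr > 1) {
    mu_cor <- 0.25 * (mu[1:(nr - 1), jj] + mu[1:(nr - 1), jj + 1] +
                        mu[2:nr, jj] + mu[2:nr, jj + 1])
    t2[2:nr, ] <- r_f[1:(nr - 1)] * mu_cor *
      (v[2:nr, jj + 1] - v[2:nr, jj]) / dz
  }
  st2 <- 2 * pi * dz * (t2[2:(nr + 1), , drop = FALSE] -
                          t2[1:nr, , drop = FALSE])
  b <- (p[, jj, drop = FALSE] - p[, jj + 1, drop = FALSE]) * AzM + st1 + st2

  # fold known boundary neighbours into the source
  b[, 1] <- b[, 1] + aW[, 1] * u_in
  b[, nz - 1] <- b[, nz - 1] + aE[, nz - 1] * u[, nz + 1]

  u_cur <- u[, jj + 1, drop = FALSE]

  # momentum residual before relaxation (normalized)
  offsum <- matrix(0, nr, nz - 1)
  if (nz > 2) {
    offsum[, 1:(nz - 2)] <- offsum[, 1:(nz - 2)] +
      aE[, 1:(nz - 2)] * u_cur[, 2:(nz - 1)]
    offsum[, 2:(nz - 1)] <- offsum[, 2:(nz - 1)] +
      aW[, 2:(nz - 1)] * u_cur[, 1:(nz - 2)]
  }
  if (nr > 1) {
    offsum[1:(nr - 1), ] <- offsum[1:(nr - 1), ] + aN[1:(nr - 1), ] *
      u_cur[2:nr, ]
    offsum[2:nr, ] <- offsum[2:nr, ] + aS[2:nr, ] * u_cur[1:(nr - 1), ]
  }
  resid <- sum(abs(ap0 * u_cur - offsum - b)[!solid_u]) /
    (sum(abs(ap0 * u_cur)[!solid_u]) + 1e-300)

  # triplets (off-diagonals; diagonal set by the caller)
  ti <- c(); tj <- c(); tx <- c()
  ii <- as.vector(row(idx)); jjv <- as.vector(col(idx)); me <- as.vector(idx)
  sol <- as.vector(solid_u)
  keep <- jjv < (nz - 1) & !sol                     # east
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] + nr)
  tx <- c(tx, -as.vector(aE)[keep])
  keep <- jjv > 1 & !sol                            # west
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] - nr)
  tx <- c(tx, -as.vector(aW)[keep])
  keep <- ii < nr & !sol                            # north
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] + 1)
  tx <- c(tx, -as.vector(aN)[keep])
  keep <- ii > 1 & !sol                             # south
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] - 1)
  tx <- c(tx, -as.vector(aS)[keep])
  # diagonal placeholder (replaced by caller through Matrix::diag<-)
  ti <- c(ti, me); tj <- c(tj, me)
  ap0v <- as.vector(ap0)
  ap0v[sol] <- 1
  tx <- c(tx, rep(0, n))
  bv <- as.vector(b); bv[sol] <- 0
  list(ti = ti, tj = tj, tx = tx, n = n,
       ap0 = ap0v, b = bv, u_cur = as.vector(u_cur),
       offsum = as.vector(offsum), residual = resid)
}

assemble_v <- function(u, v, p, mu, rho, nr, nz, dr, dz, r_c, r_f, Az,
                       fluid_cell) {
  if (nr < 2) return(NULL)
  ii <- seq_len(nr - 1)                     # interior radial faces
  n <- (nr - 1) * nz
  idx <- matrix(seq_len(n), nr - 1, nz)
  vol <- 2 * pi * r_f[ii] * dr * dz
  AnV <- 2 * pi * r_c[ii + 1] * dz          # CV outer radial face
  AsV <- 2 * pi * r_c[ii] * dz
  AzV <- 2 * pi * r_f[ii] * dr

  vc <- v[2:nr, , drop = FALSE]             # current interior v faces
  Fn <- rho * 0.5 * (v[2:nr, , drop = FALSE] +
                       v[3:(nr + 1), , drop = FALSE]) * matrix(AnV, nr - 1, nz)
  Fs <- rho * 0.5 * (v[1:(nr - 1), , drop = FALSE] +
                       v[2:nr, , drop = FALSE]) * matrix(AsV, nr - 1, nz)
  ue <- 0.5 * (u[ii, 2:(nz + 1), drop = FALSE] +
                 u[ii + 1, 2:(nz + 1), drop = FALSE])
  uw <- 0.5 * (u[ii, 1:nz, drop = FALSE] + u[ii + 1, 1:nz, drop = FALSE])
  Fe <- rho * ue * matrix(AzV, nr - 1, nz)
  Fw <- rho * uw * matrix(AzV, nr - 1, nz)

  Dn <- mu[ii + 1, , drop = FALSE] * matrix(AnV, nr - 1, nz) / dr
  Ds <- mu[ii, , drop = FALSE] * matrix(AsV, nr - 1, nz) / dr
  mu_cor <- matrix(0, nr - 1, nz)           # at (r_f, z_f[j]) corners
  if (nz > 1) {
    mu_cor[, 1:(nz - 1)] <- 0.25 * (mu[ii, 1:(nz - 1)] + mu[ii + 1, 1:(nz - 1)] +
                                      mu[ii, 2:nz] + mu[ii + 1, 2:nz])
  }
  De <- mu_cor * matrix(AzV, nr - 1, nz) / dz
  De[, nz] <- 0                             # zero-gradient outlet
  muw_in <- 0.5 * (mu[ii, 1] + mu[ii + 1, 1])
  Dw <- matrix(0, nr - 1, nz)
  if (nz > 1) Dw[, 2:nz] <- De[, 1:(nz - 1)]
  Dw[, 1] <- muw_in * AzV / (dz / 2)        # v = 0 on the inlet plane

  aN <- Dn + pmax(-Fn, 0)
  aS <- Ds + pmax(Fs, 0)
  aE <- De + pmax(-Fe, 0)
  aW <- Dw + pmax(Fw, 0)
  curv <- 2 * (0.5 * (mu[ii, , drop = FALSE] + mu[ii + 1, , drop = FALSE])) *
    matrix(vol, nr - 1, nz) / matrix(r_f[ii]^2, nr - 1, nz)
  ap0 <- aN + aS + aE + aW + (Fn - Fs + Fe - Fw) + curv

  b <- (p[ii, , drop = FALSE] - p[ii + 1, , drop = FALSE]) *
    matrix(2 * pi * r_f[ii] * dz, nr - 1, nz)

  solid_v <- !(fluid_cell[ii, , drop = FALSE] &
                 fluid_cell[ii + 1, , drop = FALSE])

  me <- as.vector(idx)
  iiv <- as.vector(row(idx)); jjv <- as.vector(col(idx))
  sol <- as.vector(solid_v)
  ti <- c(); tj <- c(); tx <- c()
  keep <- iiv < (nr - 1) & !sol
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] + 1)
  tx <- c(tx, -as.vector(aN)[keep])
  keep <- iiv > 1 & !sol
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] - 1)
  tx <- c(tx, -as.vector(aS)[keep])
  keep <- jjv < nz & !sol
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] + (nr - 1))
  tx <- c(tx, -as.vector(aE)[keep])
  keep <- jjv > 1 & !sol
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] - (nr - 1))
  tx <- c(tx, -as.vector(aW)[keep])
  ti <- c(ti, me); tj <- c(tj, me); tx <- c(tx, rep(0, n))
  ap0v <- as.vector(ap0); ap0v[sol] <- 1
  bv <- as.vector(b); bv[sol] <- 0
  list(ti = ti, tj = tj, tx = tx, n = n, ap0 = ap0v, b = bv,
       v_cur = as.vector(vc))
}

pressure_correction <- function(u, v, rho, nr, nz, dz, Az, r_f, d_u, d_v,
                                solid_p) {
  # net mass imbalance per cell (inflow positive)
  conv_z <- rho * matrix(Az, nr, nz) * (u[, 1:nz] - u[, 2:(nz + 1)])
  rfv_lo <- c(0, r_f[seq_len(nr - 1)]) * v[1:nr, , drop = FALSE]
  rfv_hi <- r_f * v[2:(nr + 1), , drop = FALSE]
  conv_r <- rho * 2 * pi * dz * (rfv_lo - rfv_hi)
  b <- conv_z + conv_r
  b[solid_p] <- 0
  mass_residual <- sum(abs(b))

  aE <- matrix(0, nr, nz); aW <- matrix(0, nr, nz)
  aN <- matrix(0, nr, nz); aS <- matrix(0, nr, nz)
  aE[, 1:(nz - 1)] <- rho * matrix(Az, nr, nz - 1) * d_u
  aW[, 2:nz] <- aE[, 1:(nz - 1)]
  if (nr > 1) {
    aN[1:(nr - 1), ] <- rho * matrix(2 * pi * r_f[seq_len(nr - 1)] * dz,
                                     nr - 1, nz) * d_v
    aS[2:nr, ] <- aN[1:(nr - 1), ]
  }
  ap <- aE + aW + aN + aS
  n <- nr * nz
  idx <- matrix(seq_len(n), nr, nz)
  me <- as.vector(idx)
  iiv <- as.vector(row(idx)); jjv <- as.vector(col(idx))
  sol <- as.vector(solid_p)
  ti <- c(); tj <- c(); tx <- c()
  keep <- jjv < nz & !sol
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] + nr)
  tx <- c(tx, -as.vector(aE)[keep])
  keep <- jjv > 1 & !sol
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] - nr)
  tx <- c(tx, -as.vector(aW)[keep])
  keep <- iiv < nr & !sol
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] + 1)
  tx <- c(tx, -as.vector(aN)[keep])
  keep <- iiv > 1 & !sol
  ti <- c(ti, me[keep]); tj <- c(tj, me[keep] - 1)
  tx <- c(tx, -as.vector(aS)[keep])
  apv <- as.vector(ap); apv[sol] <- 1
  bv <- as.vector(b)
  # pin the reference cell (outlet corner) to make the Neumann system regular
  pin <- idx[1, nz]
  ti <- c(ti, me); tj <- c(tj, me); tx <- c(tx, apv * 0)
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n))
  Matrix::diag(A) <- apv
  # overwrite pin row with identity
  A[pin, ] <- 0; A[pin, pin] <- 1; bv[pin] <- 0
  pp <- as.numeric(Matrix::solve(A, bv))
  list(pp = matrix(pp, nr, nz), mass_residual = mass_residual)
}

update_viscosity <- function(u, v, mu_old, fluid, r_c, dr, dz, relax) {
  nr <- length(r_c); nz <- ncol(mu_old)
  u_c <- 0.5 * (u[, 1:nz, drop = FALSE] + u[, 2:(nz + 1), drop = FALSE])
  v_c <- 0.5 * (v[1:nr, , drop = FALSE] + v[2:(nr + 1), , drop = FALSE])
  dudz <- (u[, 2:(nz + 1), drop = FALSE] - u[, 1:nz, drop = FALSE]) / dz
  dvdr <- (v[2:(nr + 1), , drop = FALSE] - v[1:nr, , drop = FALSE]) / dr
  # du/dr: average of radial-face gradients, wall via half-cell no-slip
  g_face <- matrix(0, nr + 1, nz)           # at faces 0..nr
  if (nr > 1) {
    g_face[2:nr, ] <- (u_c[2:nr, , drop = FALSE] -
                         u_c[1:(nr - 1), , drop = FALSE]) / dr
  }
  g_face[nr + 1, ] <- (0 - u_c[nr, ]) / (dr / 2)
  dudr <- 0.5 * (g_face[1:nr, , drop = FALSE] + g_face[2:(nr + 1), , drop = FALSE])
  # dv/dz at centres (central where possible)
  dvdz <- matrix(0, nr, nz)
  if (nz > 2) {
    dvdz[, 2:(nz - 1)] <- (v_c[, 3:nz, drop = FALSE] -
                             v_c[, 1:(nz - 2), drop = FALSE]) / (2 * dz)
  }
  vtheta <- sweep(v_c, 1, r_c, "/")
  gam <- sqrt(2 * (dudz^2 + dvdr^2 + vtheta^2) + (dudr + dvdz)^2)
  mu_new <- effective_viscosity(fluid, pmax(gam, fluid$gamma_floor))
  mu <- relax * mu_new + (1 - relax) * mu_old
  attr(mu, "shear_rate") <- gam
  mu
}

#' Extract a radial velocity profile
#'
#' Axial velocity versus radius at the grid station nearest the requested
#' axial fraction.
#'
#' @param solution A `cow_field_solution`.
#' @param axial_station Fraction of the segment length in `[0, 1]`.
#' @return A tibble with `r` (m), `u` (m/s), and the station `z` (m).
#' @export
extract_profile <- function(solution, axial_station) {
  stopifnot(inherits(solution, "cow_field_solution"))
  check_number(axial_station, "axial_station", min = 0, max = 1)
  nz <- solution$grid$n_axial
  nr <- solution$grid$n_radial
  j <- round(axial_station * nz)            # face index 0..nz
  dr <- solution$grid$r_max / nr
  tibble(r = (seq_len(nr) - 0.5) * dr,
         u = solution$u[, j + 1],
         z = j * solution$grid$length / nz)
}

#' Grid-convergence study against the analytic developed profile
#'
#' Solves the same case on successively refined grids (cell counts doubled
#' per level) and reports the L2 error of the developed velocity profile
#' against the closed-form Casson (or Poiseuille) solution. Errors decrease
#' monotonically with refinement for a consistent discretization. A zero
#' inlet returns a table of zero errors (nothing to converge to).
#'
#' @param base_grid An [axisymmetric_grid()] (straight tube).
#' @param fluid A [casson_fluid()].
#' @param inlet An [inlet_spec()] or peak velocity in m/s.
#' @param outlet_pressure Outlet pressure, Pa.
#' @param settings A [solver_settings()].
#' @param refinements Number of grid levels (>= 2).
#' @param station Axial fraction at which the profile is compared.
#' @return A tibble with `level`, `n_radial`, `n_axial`, `l2_error`.
#' @export
grid_convergence_study <- function(base_grid, fluid, inlet,
                                   outlet_pressure = 0,
                                   settings = solver_settings(),
                                   refinements = 3, station = 0.9) {
  if (refinements < 2) {
    abort("`refinements` must be >= 2.", class = "cowflow_invalid_input")
  }
  if (is.numeric(inlet)) inlet <- inlet_spec(inlet)
  levels <- seq_len(refinements) - 1L
  if (inlet$peak_velocity == 0) {
    return(tibble(level = levels,
                  n_radial = base_grid$n_radial * 2^levels,
                  n_axial = base_grid$n_axial * 2^levels,
                  l2_error = 0))
  }
  purrr::map_dfr(levels, function(lv) {
    g <- axisymmetric_grid(base_grid$n_radial * 2^lv,
                           base_grid$n_axial * 2^lv,
                           base_grid$length, base_grid$radius)
    sol <- solve_segment(g, fluid, inlet, outlet_pressure, settings)
    tibble(level = lv, n_radial = g$n_radial, n_axial = g$n_axial,
           l2_error = developed_profile_error(sol, station))
  })
}

# radius-weighted L2 error of the numerical profile vs the closed form
developed_profile_error <- function(solution, station = 0.9) {
  pr <- extract_profile(solution, station)
  fl <- solution$fluid
  R <- solution$grid$radius
  G <- invert_peak_to_gradient(fl, R, solution$inlet$peak_velocity)
  ua <- casson_velocity_profile(fl, R, G, pr$r)
  w <- pr$r
  sqrt(sum(w * (pr$u - ua)^2) / sum(w * ua^2))
}

#' @export
autoplot.cow_field_solution <- function(object, ...) {
  nz <- object$grid$n_axial; nr <- object$grid$n_radial
  dr <- object$grid$r_max / nr; dz <- object$grid$length / nz
  df <- tidyr::expand_grid(j = seq_len(nz), i = seq_len(nr))
  df$z <- (df$j - 0.5) * dz
  df$r <- (df$i - 0.5) * dr
  df$u <- purrr::map2_dbl(df$i, df$j, function(i, j) {
    0.5 * (object$u[i, j] + object$u[i, j + 1])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$r,
                                   fill = .data$u)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "u (m/s)") +
    ggplot2::labs(x = "axial position (m)", y = "radius (m)",
                  title = "Axial velocity field") +
    ggplot2::theme_minimal()
}
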