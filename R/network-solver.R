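#' Per-phase boundary conditions
#'
#' One steady solve is done per cardiac phase (PSV, EDV, MFV): Doppler
#' envelope velocities at the four inlets and a uniform pressure at all
#' outlets (systolic pressure for the PSV phase, diastolic for EDV, mean
#' arterial pressure for MFV). Inlet velocities are interpreted as the
#' Doppler envelope peak, i.e. the centreline velocity of the inlet segment.
#'
#' @param phase One of "PSV", "EDV", "MFV".
#' @param inlet_velocity_cms Named vector of inlet peak velocities in cm/s;
#'   names among `ICA_L`, `ICA_R`, `VA_L`, `VA_R`. Missing inlets get 0.
#' @param outlet_pressure_mmhg Uniform outlet pressure, mmHg.
#' @return A list of class `cow_phase_bc`.
#' @export
#' @examples
#' phase_bc("PSV", c(ICA_L = 60, ICA_R = 60, VA_L = 40, VA_R = 40), 130)
phase_bc <- function(phase, inlet_velocity_cms, outlet_pressure_mmhg) {
  phase <- match.arg(phase, c("PSV", "EDV", "MFV"))
  v <- inlet_velocity_cms
  if (is.null(names(v)) || !all(names(v) %in% c("ICA_L", "ICA_R", "VA_L", "VA_R"))) {
    abort("`inlet_velocity_cms` must be named with inlet segment names.",
          class = "cowflow_invalid_input")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("Inlet velocities must be finite and non-negative.",
          class = "cowflow_invalid_input")
  }
  if (all(v == 0)) {
    abort("At least one inlet velocity must be positive.",
          class = "cowflow_invalid_input")
  }
  check_number(outlet_pressure_mmhg, "outlet_pressure_mmhg", min = 0)
  structure(list(phase = phase,
                 inlet_velocity_cms = v,
                 outlet_pressure_pa = mmhg_to_pa(outlet_pressure_mmhg)),
            class = "cow_phase_bc")
}

# signed Casson segment flow: positive from -> to
segment_flow_signed <- function(fluid, radius, length, dp) {
  G <- abs(dp) / length
  sign(dp) * casson_flow_scalar(fluid, radius, G)
}

# derivative dQ/d(dp) of the signed segment law
segment_flow_deriv <- function(fluid, radius, length, dp) {
  G <- abs(dp) / length
  tau_w <- G * radius / 2
  g_newt <- pi * radius^4 / (8 * fluid$eta_c * length)
  if (tau_w <= fluid$tau_c) return(g_newt * 1e-8)  # Jacobian floor below yield
  xi <- fluid$tau_c / tau_w
  max(g_newt * casson_flow_factor_dG(xi), g_newt * 1e-8)
}

#' Solve steady flow in a Circle-of-Willis network
#'
#' Reduced-order solver: every segment obeys the closed-form Casson pipe law,
#' every junction conserves mass (Kirchhoff balance), inlet segments carry the
#' volumetric flow implied by their Doppler peak velocity (the gradient whose
#' Casson profile has that centreline velocity, so the peak-to-mean conversion
#' is solved self-consistently per inlet), and outlets carry the phase
#' pressure. Unknown junction pressures are found by damped Newton iteration
#' on the nodal mass balance, started from the Newtonian linear-network
#' solution; loops through the communicating arteries are handled naturally by
#' the nodal formulation.
#'
#' @param network A `cow_network`.
#' @param fluid A [casson_fluid()].
#' @param bc A [phase_bc()].
#' @param tolerance Relative mass-balance tolerance (worst node residual over
#'   total inflow).
#' @param max_iter Maximum Newton iterations.
#' @return A `cow_network_solution`: tibbles `nodes` (`node`,
#'   `pressure_pa`) and `segments` (`id`, `name`, `flow_m3s`,
#'   `mean_velocity_cms`, `peak_velocity_cms`, `flow_ml_min`), plus `phase`
#'   and convergence info.
#' @export
solve_network <- function(network, fluid, bc, tolerance = 1e-9,
                          max_iter = 100) {
  stopifnot(inherits(network, "cow_network"), inherits(fluid, "casson_fluid"),
            inherits(bc, "cow_phase_bc"))
  rep <- validate_network(network)
  if (nrow(rep) > 0) {
    abort(paste0("Invalid network: ", paste(rep$violation, collapse = "; ")),
          class = "cowflow_validation_error")
  }
  s <- network$segments
  inl <- s[s$role == "inlet", ]
  missing_in <- setdiff(names(bc$inlet_velocity_cms), inl$name)
  if (length(missing_in) > 0) {
    abort(paste0("Inlets absent from network: ",
                 paste(missing_in, collapse = ", ")),
          class = "cowflow_validation_error")
  }

  # fixed inlet flows from Doppler peak velocity (self-consistent profile)
  q_in <- stats::setNames(rep(0, nrow(inl)), inl$name)
  for (k in seq_len(nrow(inl))) {
    v <- unname(bc$inlet_velocity_cms[inl$name[k]])
    if (is.na(v)) v <- 0
    if (v > 0) {
      G <- invert_peak_to_gradient(fluid, inl$radius_m[k], cms_to_ms(v))
      q_in[inl$name[k]] <- casson_flow_scalar(fluid, inl$radius_m[k], G)
    }
  }
  total_in <- sum(q_in)

  outlet_nodes <- unique(s$to[s$role == "outlet"])
  inlet_entry <- unique(s$from[s$role == "inlet"])
  interior <- s[s$role != "inlet", ]
  unknown <- setdiff(unique(c(interior$from, interior$to)), outlet_nodes)
  p_out <- bc$outlet_pressure_pa

  # flow injected at each unknown node by the fixed-flow inlet segments
  inject <- stats::setNames(rep(0, length(unknown)), unknown)
  for (k in seq_len(nrow(inl))) {
    nd <- inl$to[k]
    if (nd %in% unknown) inject[nd] <- inject[nd] + q_in[inl$name[k]]
  }

  node_p <- function(x, nd) {
    ifelse(nd %in% outlet_nodes, p_out, x[nd])
  }

  residual <- function(x) {
    r <- stats::setNames(rep(0, length(unknown)), unknown)
    for (k in seq_len(nrow(interior))) {
      pa <- node_p(x, interior$from[k]); pb <- node_p(x, interior$to[k])
      q <- segment_flow_signed(fluid, interior$radius_m[k],
                               interior$length_m[k], pa - pb)
      if (interior$from[k] %in% unknown) {
        r[interior$from[k]] <- r[interior$from[k]] - q
      }
      if (interior$to[k] %in% unknown) {
        r[interior$to[k]] <- r[interior$to[k]] + q
      }
    }
    r + inject
  }

  jacobian <- function(x) {
    J <- matrix(0, length(unknown), length(unknown),
                dimnames = list(unknown, unknown))
    for (k in seq_len(nrow(interior))) {
      a <- interior$from[k]; b <- interior$to[k]
      g <- segment_flow_deriv(fluid, interior$radius_m[k],
                              interior$length_m[k],
                              node_p(x, a) - node_p(x, b))
      if (a %in% unknown) J[a, a] <- J[a, a] - g
      if (b %in% unknown) J[b, b] <- J[b, b] - g
      if (a %in% unknown && b %in% unknown) {
        J[a, b] <- J[a, b] + g
        J[b, a] <- J[b, a] + g
      }
    }
    J
  }

  # Newtonian linear-network solution as the initial guess (exact for tau_c=0)
  g_lin <- pi * interior$radius_m^4 / (8 * fluid$eta_c * interior$length_m)
  A <- matrix(0, length(unknown), length(unknown),
              dimnames = list(unknown, unknown))
  bvec <- inject
  for (k in seq_len(nrow(interior))) {
    a <- interior$from[k]; b <- interior$to[k]; g <- g_lin[k]
    if (a %in% unknown) A[a, a] <- A[a, a] + g
    if (b %in% unknown) A[b, b] <- A[b, b] + g
    if (a %in% unknown && b %in% unknown) {
      A[a, b] <- A[a, b] - g
      A[b, a] <- A[b, a] - g
    }
    if (a %in% unknown && !(b %in% unknown)) bvec[a] <- bvec[a] + g * p_out
    if (b %in% unknown && !(a %in% unknown)) bvec[b] <- bvec[b] + g * p_out
  }
  x <- stats::setNames(drop(solve(A, bvec)), unknown)

  # damped Newton on the nodal balance
  scale_q <- max(total_in, 1e-12)
  r <- residual(x)
  iter <- 0L
  converged <- max(abs(r)) <= tolerance * scale_q
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    dx <- drop(solve(jacobian(x), -r))
    step <- 1
    for (h in 0:30) {
      xn <- x + step * dx
      rn <- residual(xn)
      if (max(abs(rn)) < max(abs(r)) || max(abs(rn)) <= tolerance * scale_q) break
      step <- step / 2
    }
    x <- xn; r <- rn
    converged <- max(abs(r)) <= tolerance * scale_q
  }
  if (!converged) {
    worst <- names(which.max(abs(r)))
    abort(sprintf(
      "Network Newton failed to converge: worst node %s, residual %.3e of inflow %.3e.",
      worst, max(abs(r)), scale_q),
      class = "cowflow_nonconvergence")
  }

  # assemble solution: segment flows and velocities, inlet entry pressures
  pres <- stats::setNames(rep(NA_real_, length(network_nodes(network))),
                          network_nodes(network))
  pres[unknown] <- x[unknown]
  pres[outlet_nodes] <- p_out
  seg_q <- numeric(nrow(s))
  for (k in seq_len(nrow(s))) {
    if (s$role[k] == "inlet") {
      seg_q[k] <- q_in[s$name[k]]
      # entry pressure from the inlet segment's own Casson pressure drop
      G <- invert_flow_to_gradient(fluid, s$radius_m[k], seg_q[k])
      pres[s$from[k]] <- pres[s$to[k]] + G * s$length_m[k]
    } else {
      seg_q[k] <- segment_flow_signed(fluid, s$radius_m[k], s$length_m[k],
                                      pres[s$from[k]] - pres[s$to[k]])
    }
  }
  peak <- vapply(seq_len(nrow(s)), function(k) {
    q <- abs(seg_q[k])
    if (q == 0) return(0)
    G <- invert_flow_to_gradient(fluid, s$radius_m[k], q)
    casson_plug_velocity(fluid, s$radius_m[k], G)
  }, numeric(1))

  structure(list(
    nodes = tibble(node = names(pres), pressure_pa = unname(pres)),
    segments = tibble(id = s$id, name = s$name, role = s$role,
                      flow_m3s = seg_q,
                      mean_velocity_cms = ms_to_cms(seg_q / (pi * s$radius_m^2)),
                      peak_velocity_cms = ms_to_cms(sign(seg_q) * peak),
                      flow_ml_min = m3s_to_mlmin(seg_q)),
    phase = bc$phase,
    iterations = iter,
    residual = max(abs(r)) / scale_q,
    total_inflow_m3s = total_in),
    class = "cow_network_solution")
}

#' @export
print.cow_network_solution <- function(x, ...) {
  cat(sprintf("<cow_network_solution> phase %s, %d segments, residual %.2e\n",
              x$phase, nrow(x$segments), x$residual))
  invisible(x)
}

#' @export
tidy.cow_network_solution <- function(x, ...) x$segments

#' @export
glance.cow_network_solution <- function(x, ...) {
  out <- x$segments$flow_m3s[x$segments$role == "outlet"]
  tibble(phase = x$phase,
         total_inflow_ml_min = m3s_to_mlmin(x$total_inflow_m3s),
         total_outflow_ml_min = m3s_to_mlmin(sum(out)),
         iterations = x$iterations,
         residual = x$residual)
}

#' Per-artery flow volumes
#'
#' Converts the signed segment flows of a converged network solution to
#' clinical flow volumes in mL/min. Total inflow equals total outflow to the
#' solver tolerance.
#'
#' @param solution A `cow_network_solution`.
#' @return A tibble with `name`, `role`, `flow_ml_min`.
#' @export
compute_flow_volumes <- function(solution) {
  stopifnot(inherits(solution, "cow_network_solution"))
  dplyr::select(solution$segments, "name", "role", "flow_ml_min")
}

#' Simulate one patient across the three cardiac phases
#'
#' Runs three independent steady solves (PSV with systolic outlet pressure,
#' EDV with diastolic, MFV with mean arterial pressure) and reads the
#' centreline velocity at the conventional insonation sites: M1 (MCA), A1
#' (ACA), P1 (PCA), BA and V4, both sides where applicable. Velocities are
#' reported as unsigned Doppler-comparable magnitudes in cm/s; flow volumes
#' come from the MFV (mean-flow) phase.
#'
#' @param network A `cow_network`.
#' @param fluid A [casson_fluid()].
#' @param bc_phases Named list with elements `PSV`, `EDV`, `MFV`, each a
#'   [phase_bc()].
#' @return A list of class `cow_patient_sim`: `sites` tibble (`artery`,
#'   `side`, `psv_cms`, `edv_cms`, `mfv_cms`, `flow_ml_min`), plus the three
#'   `cow_network_solution`s in `$solutions`.
#' @export
simulate_patient <- function(network, fluid, bc_phases) {
  if (!all(c("PSV", "EDV", "MFV") %in% names(bc_phases))) {
    abort("`bc_phases` must contain PSV, EDV and MFV boundary conditions.",
          class = "cowflow_invalid_input")
  }
  sols <- lapply(c(PSV = "PSV", EDV = "EDV", MFV = "MFV"), function(ph) {
    tryCatch(solve_network(network, fluid, bc_phases[[ph]]),
             error = function(e) {
               abort(sprintf("Phase %s solve failed: %s", ph,
                             conditionMessage(e)),
                     class = "cowflow_phase_error")
             })
  })
  site_map <- measurement_sites()
  site_map <- site_map[site_map$segment %in% network$segments$name, ]
  vel <- function(sol, seg) {
    abs(sol$segments$peak_velocity_cms[sol$segments$name == seg])
  }
  flow <- function(seg) {
    abs(sols$MFV$segments$flow_ml_min[sols$MFV$segments$name == seg])
  }
  sites <- tibble(
    artery = site_map$artery,
    side = site_map$side,
    psv_cms = vapply(site_map$segment, function(sg) vel(sols$PSV, sg), 1,
                     USE.NAMES = FALSE),
    edv_cms = vapply(site_map$segment, function(sg) vel(sols$EDV, sg), 1,
                     USE.NAMES = FALSE),
    mfv_cms = vapply(site_map$segment, function(sg) vel(sols$MFV, sg), 1,
                     USE.NAMES = FALSE),
    flow_ml_min = vapply(site_map$segment, flow, 1, USE.NAMES = FALSE))
  structure(list(sites = sites, solutions = sols),
            class = "cow_patient_sim")
}

# conventional TCCD measurement sites (segment midpoints)
measurement_sites <- function() {
  tibble(
    artery = c("MCA", "MCA", "ACA", "ACA", "PCA", "PCA", "BA", "V4", "V4"),
    side = c("right", "left", "right", "left", "right", "left", NA,
             "right", "left"),
    segment = c("MCA_M1_R", "MCA_M1_L", "ACA_A1_R", "ACA_A1_L",
                "PCA_P1_R", "PCA_P1_L", "BA", "V4_R", "V4_L"))
}

#' @export
tidy.cow_patient_sim <- function(x, ...) x$sites
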