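# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the ICC oracle goes through stats::aov, the
# profile oracle integrates the shear-rate ODE numerically, and the network
# oracle solves the linear resistance system directly.

# ICC (two-way, absolute agreement, single measures) from an aov decomposition
oracle_icc_anova <- function(x, y) {
  n <- length(x); k <- 2
  d <- data.frame(score = c(x, y),
                  subject = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(c("a", "b"), each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# velocity profile by integrating du/dr = -shear_rate(r) from the wall inward
# (trapezoidal, fine grid), independent of the closed-form profile
oracle_ode_profile <- function(fluid, R, G, r_eval, n_grid = 20000) {
  rp <- min(2 * fluid$tau_c / G, R)
  gam <- function(r) {
    tau <- G * r / 2
    ifelse(tau > fluid$tau_c,
           (sqrt(tau) - sqrt(fluid$tau_c))^2 / fluid$eta_c, 0)
  }
  rg <- seq(0, R, length.out = n_grid)
  g <- gam(rg)
  dr <- rg[2] - rg[1]
  seg_area <- (g[-1] + g[-n_grid]) / 2 * dr     # integral over [rg_i, rg_i+1]
  u <- c(rev(cumsum(rev(seg_area))), 0)         # u(rg_i) = int_{rg_i}^R gamma
  stats::approx(rg, u, xout = pmax(r_eval, rp))$y
}

# flow rate by quadrature of the analytic profile over the cross-section
oracle_flow_quadrature <- function(fluid, R, G) {
  2 * pi * stats::integrate(function(r) {
    r * casson_velocity_profile(fluid, R, G, r)
  }, 0, R, rel.tol = 1e-12)$value
}

# linear (Newtonian) nodal network solution, written independently
oracle_linear_network <- function(network, eta, q_in, outlet_pressure) {
  s <- network$segments
  interior <- s[s$role != "inlet", ]
  outlet_nodes <- unique(s$to[s$role == "outlet"])
  unknown <- setdiff(unique(c(interior$from, interior$to)), outlet_nodes)
  g <- pi * interior$radius_m^4 / (8 * eta * interior$length_m)
  A <- matrix(0, length(unknown), length(unknown),
              dimnames = list(unknown, unknown))
  b <- stats::setNames(rep(0, length(unknown)), unknown)
  for (nm in names(q_in)) {
    nd <- s$to[s$name == nm]
    if (nd %in% unknown) b[nd] <- b[nd] + q_in[[nm]]
  }
  for (k in seq_len(nrow(interior))) {
    a <- interior$from[k]; bb <- interior$to[k]
    if (a %in% unknown) A[a, a] <- A[a, a] + g[k]
    if (bb %in% unknown) A[bb, bb] <- A[bb, bb] + g[k]
    if (a %in% unknown && bb %in% unknown) {
      A[a, bb] <- A[a, bb] - g[k]; A[bb, a] <- A[bb, a] - g[k]
    }
    if (a %in% unknown && !(bb %in% unknown)) b[a] <- b[a] + g[k] * outlet_pressure
    if (bb %in% unknown && !(a %in% unknown)) b[bb] <- b[bb] + g[k] * outlet_pressure
  }
  p <- drop(solve(A, b))
  pr <- function(nd) if (nd %in% outlet_nodes) outlet_pressure else p[[nd]]
  flows <- vapply(seq_len(nrow(interior)), function(k) {
    g[k] * (pr(interior$from[k]) - pr(interior$to[k]))
  }, numeric(1))
  stats::setNames(flows, interior$name)
}

# hand-built small test networks (named so that validate_network accepts them)
make_chain_network <- function(r1 = 2.5e-3, r2 = 2e-3) {
  seg <- tibble::tibble(
    id = c("ICA_L", "MCA_M1_L"),
    name = id,
    from = c("n_in", "n0"), to = c("n0", "n_out"),
    length_m = c(0.1, 0.03),
    radius_m = c(r1, r2),
    role = c("inlet", "outlet"))
  structure(list(segments = seg, variant = anatomical_variant()),
            class = "cow_network")
}

make_parallel_network <- function(r_a = 2e-3, r_b = 2e-3 / sqrt(2)) {
  seg <- tibble::tibble(
    id = c("ICA_L", "MCA_M1_L", "MCA_M1_R"),
    name = id,
    from = c("n_in", "n0", "n0"), to = c("n0", "n_out1", "n_out2"),
    length_m = c(0.1, 0.02, 0.02),
    radius_m = c(2.5e-3, r_a, r_b),
    role = c("inlet", "outlet", "outlet"))
  structure(list(segments = seg, variant = anatomical_variant()),
            class = "cow_network")
}

symmetric_bc <- function(phase = "PSV", ica = 60, va = 40, press = 130) {
  phase_bc(phase, c(ICA_L = ica, ICA_R = ica, VA_L = va, VA_R = va), press)
}

# radius-weighted L2 error of a developed numerical profile vs the closed form
developed_l2_error <- function(sol, station = 0.9) {
  pr <- extract_profile(sol, station)
  G <- invert_peak_to_gradient(sol$fluid, sol$grid$radius,
                               sol$inlet$peak_velocity)
  ua <- casson_velocity_profile(sol$fluid, sol$grid$radius, G, pr$r)
  sqrt(sum(pr$r * (pr$u - ua)^2) / sum(pr$r * ua^2))
}

# pairs from stored true sites re-noised at a given level (for monotonicity)
renoise_pairs <- function(sites, sd_mult, seed = 99) {
  noise <- tccd_noise_params(sd_mult = sd_mult)
  meas <- synthesize_tccd(sites, noise, seed = seed)
  cowflow:::pair_tables(sites, meas)
}
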