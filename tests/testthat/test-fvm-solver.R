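# Desk-scale verification of the pressure-correction solver against the
# closed-form developed solutions. Unit tests run on modest grids; the
# reference-resolution case lives in the acceptance suite.

test_that("zero inflow gives the exact rest state", {
  g <- axisymmetric_grid(8, 16, length = 0.01, radius = 2e-3)
  sol <- solve_segment(g, casson_fluid(), 0, outlet_pressure = 750)
  expect_true(sol$converged)
  expect_identical(max(abs(sol$u)), 0)
  expect_true(all(sol$p == 750))
})

test_that("Newtonian developed flow reproduces the Poiseuille parabola", {
  fn <- casson_fluid(tau_c = 0)
  g <- axisymmetric_grid(16, 64, length = 0.02, radius = 2e-3)
  sol <- solve_segment(g, fn, inlet_spec(0.5), 0)
  expect_true(sol$converged)
  expect_lt(sol$mass_error, 1e-6)
  expect_lt(developed_l2_error(sol), 0.02)
  # monotone toward the no-slip wall, maximum on the axis
  pr <- extract_profile(sol, 0.9)
  expect_true(all(diff(pr$u) < 0))
  expect_lt(pr$u[length(pr$u)], 0.1 * max(pr$u))   # wall-adjacent cell centre
  expect_identical(which.max(pr$u), 1L)
})

test_that("Casson developed flow matches the analytic profile and gradient", {
  fl <- casson_fluid()
  g <- axisymmetric_grid(16, 64, length = 0.02, radius = 2e-3)
  sol <- solve_segment(g, fl, inlet_spec(0.6), 0)
  expect_true(sol$converged)
  expect_lt(developed_l2_error(sol), 0.02)
  # pressure drop per length matches the inverted pipe law within 3 %
  G <- invert_peak_to_gradient(fl, 2e-3, 0.6)
  nz <- g$n_axial
  pbar <- colMeans(sol$p)
  dpdz <- (pbar[round(0.25 * nz)] - pbar[round(0.75 * nz)]) / (0.5 * g$length)
  expect_equal(dpdz, G, tolerance = 0.03)
  # viscosity field honours the constitutive law cell by cell
  # (Picard-lagged by one outer iteration, hence the loose tolerance)
  expect_equal(sol$mu[, round(0.9 * nz)],
               effective_viscosity(fl, sol$shear_rate[, round(0.9 * nz)]),
               tolerance = 1e-3)
})

test_that("every converged solution conserves mass locally and globally", {
  fl <- casson_fluid()
  for (peak in c(0.2, 0.6)) {
    sol <- solve_segment(axisymmetric_grid(12, 32, length = 0.015,
                                           radius = 1.5e-3),
                         fl, inlet_spec(peak), 0)
    expect_true(sol$converged)
    expect_lt(sol$mass_error, 1e-6)
    expect_lt(tail(sol$residual_history$mass_residual, 1), 1e-6)
  }
})

test_that("profile extraction validates its station and finds the peak on axis", {
  fl <- casson_fluid()
  sol <- solve_segment(axisymmetric_grid(12, 32, length = 0.015,
                                         radius = 2e-3),
                       fl, inlet_spec(0.4), 0)
  expect_error(extract_profile(sol, 1.2), class = "cowflow_invalid_input")
  pr <- extract_profile(sol, 0.5)
  expect_identical(which.max(pr$u), 1L)
  expect_identical(nrow(pr), 12L)
})

test_that("grid refinement reduces the developed-profile error monotonically", {
  fn <- casson_fluid(tau_c = 0)
  base <- axisymmetric_grid(8, 16, length = 0.01, radius = 2e-3)
  tab <- grid_convergence_study(base, fn, 0.5, refinements = 3)
  expect_identical(nrow(tab), 3L)
  expect_true(all(diff(tab$l2_error) < 0))
  # Casson case: finest grid beats the coarsest
  tabc <- grid_convergence_study(base, casson_fluid(), 0.5, refinements = 2)
  expect_lt(tabc$l2_error[2], tabc$l2_error[1])
  # zero-velocity guard: nothing to converge to, error table of zeros
  tab0 <- grid_convergence_study(base, fn, 0, refinements = 2)
  expect_identical(tab0$l2_error, c(0, 0))
  expect_error(grid_convergence_study(base, fn, 0.5, refinements = 1),
               class = "cowflow_invalid_input")
})

test_that("extra corrector loops do not worsen the mass residual", {
  fl <- casson_fluid()
  g <- axisymmetric_grid(12, 32, length = 0.015, radius = 2e-3)
  res_after <- function(nc) {
    s <- solver_settings(n_corrector_loops = nc, max_outer_iterations = 25,
                         residual_tolerance = 1e-30)
    e <- tryCatch(solve_segment(g, fl, inlet_spec(0.4), 0, s),
                  error = function(x) x)
    tail(e$residual_history$mass_residual, 1)
  }
  r1 <- res_after(1); r2 <- res_after(2); r3 <- res_after(3)
  expect_lte(r2, r1 * 1.05)
  expect_lte(r3, r2 * 1.05)
})

test_that("the scheme converges without the momentum predictor", {
  fl <- casson_fluid()
  g <- axisymmetric_grid(10, 24, length = 0.012, radius = 2e-3)
  s <- solver_settings(momentum_predictor = FALSE,
                       max_outer_iterations = 3000)
  sol <- solve_segment(g, fl, inlet_spec(0.4), 0, s)
  expect_true(sol$converged)
  expect_lt(developed_l2_error(sol), 0.05)
})

test_that("non-convergence raises a diagnostic carrying the residual history", {
  fl <- casson_fluid()
  g <- axisymmetric_grid(10, 24, length = 0.012, radius = 2e-3)
  s <- solver_settings(max_outer_iterations = 3, residual_tolerance = 1e-12)
  err <- tryCatch(solve_segment(g, fl, inlet_spec(0.4), 0, s),
                  error = function(e) e)
  expect_s3_class(err, "cowflow_nonconvergence")
  expect_s3_class(err$residual_history, "tbl_df")
  expect_identical(nrow(err$residual_history), 3L)
})

test_that("a flat inlet develops toward the analytic peak velocity", {
  fl <- casson_fluid()
  g <- axisymmetric_grid(16, 96, length = 0.04, radius = 2e-3)
  sol <- solve_segment(g, fl, inlet_spec(0.35, profile = "flat"), 0)
  pr_in <- extract_profile(sol, 0.05)
  pr_out <- extract_profile(sol, 0.95)
  expect_gt(max(pr_out$u), max(pr_in$u))   # centreline accelerates
  expect_lt(max(pr_out$u),
            1.05 * casson_pipe_flow(fl, 2e-3,
                                    invert_flow_to_gradient(fl, 2e-3,
                                                            sol$q_in))$peak_velocity)
})
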