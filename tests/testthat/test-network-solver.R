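test_that("a single inlet-outlet chain conserves flow and follows areas", {
  fl <- casson_fluid()
  net <- make_chain_network(r1 = 2.5e-3, r2 = 2e-3)
  bc <- phase_bc("PSV", c(ICA_L = 50), 120)
  sol <- solve_network(net, fl, bc)
  q <- sol$segments$flow_m3s
  expect_equal(q[1], q[2], tolerance = 1e-9)
  # velocities scale with inverse area
  v_ratio <- sol$segments$mean_velocity_cms[2] /
    sol$segments$mean_velocity_cms[1]
  expect_equal(v_ratio, (2.5e-3 / 2e-3)^2, tolerance = 1e-10)
  # the inlet peak velocity is honoured
  expect_equal(sol$segments$peak_velocity_cms[1], 50, tolerance = 1e-6)
})

test_that("mirror-symmetric anatomy and inlets give mirror-symmetric flows", {
  fl <- casson_fluid()
  sol <- solve_network(build_cow_template(), fl, symmetric_bc())
  s <- sol$segments
  pairs <- list(c("MCA_M1_L", "MCA_M1_R"), c("ACA_A1_L", "ACA_A1_R"),
                c("PCA_P2_L", "PCA_P2_R"), c("V4_L", "V4_R"),
                c("PComm_L", "PComm_R"))
  for (pp in pairs) {
    ql <- s$flow_m3s[s$name == pp[1]]; qr <- s$flow_m3s[s$name == pp[2]]
    expect_equal(ql, qr, tolerance = 1e-8 * max(abs(ql), 1e-12))
  }
  # the anterior communicating artery carries nothing under symmetry
  expect_lt(abs(s$flow_m3s[s$name == "AComm"]),
            1e-8 * sum(abs(s$flow_m3s[s$role == "inlet"])))
})

test_that("parallel Newtonian branches split as the fourth power of radius", {
  fn <- casson_fluid(tau_c = 0)
  net <- make_parallel_network(r_a = 2e-3, r_b = 2e-3 / sqrt(2))
  sol <- solve_network(net, fn, phase_bc("PSV", c(ICA_L = 50), 120))
  q <- sol$segments$flow_m3s
  expect_equal(q[2] / q[3], 4, tolerance = 1e-6)
  expect_equal(q[1], q[2] + q[3], tolerance = 1e-9)
})

test_that("the Newtonian limit agrees with the direct linear solve to 1e-8", {
  fn <- casson_fluid(tau_c = 0)
  net <- build_cow_template()
  bc <- symmetric_bc(ica = 55, va = 35)
  sol <- solve_network(net, fn, bc)
  # independent inlet flows: parabolic profile peak -> Q = v_peak A / 2
  inl <- net$segments[net$segments$role == "inlet", ]
  v <- c(ICA_L = 55, ICA_R = 55, VA_L = 35, VA_R = 35) / 100
  q_in <- stats::setNames(v[inl$name] * pi * inl$radius_m^2 / 2, inl$name)
  oracle <- oracle_linear_network(net, fn$eta_c, q_in,
                                  mmhg_to_pa(130))
  got <- sol$segments$flow_m3s[match(names(oracle), sol$segments$name)]
  expect_equal(got, unname(oracle), tolerance = 1e-8)
})

test_that("scaling all inlet velocities scales Newtonian flows linearly", {
  fn <- casson_fluid(tau_c = 0)
  net <- build_cow_template()
  s1 <- solve_network(net, fn, symmetric_bc(ica = 40, va = 25))
  s2 <- solve_network(net, fn, symmetric_bc(ica = 80, va = 50))
  nz <- abs(s1$segments$flow_m3s) > 1e-15
  expect_equal(s2$segments$flow_m3s[nz] / s1$segments$flow_m3s[nz],
               rep(2, sum(nz)), tolerance = 1e-8)
  # Casson: all flows increase, ordering preserved
  fl <- casson_fluid()
  c1 <- solve_network(net, fl, symmetric_bc(ica = 40, va = 25))
  c2 <- solve_network(net, fl, symmetric_bc(ica = 80, va = 50))
  big <- abs(c1$segments$flow_m3s) > 1e-12
  expect_true(all(abs(c2$segments$flow_m3s[big]) >
                    abs(c1$segments$flow_m3s[big])))
  expect_identical(order(abs(c2$segments$flow_m3s[big])),
                   order(abs(c1$segments$flow_m3s[big])))
})

test_that("unilateral carotid narrowing induces contralateral collateral flow", {
  fl <- casson_fluid()
  net <- build_cow_template(anatomical_variant(ica_left_factor = 0.7))
  sol <- solve_network(net, fl, symmetric_bc())
  s <- sol$segments
  # AComm oriented left -> right: compensation flows right -> left (negative)
  expect_lt(s$flow_m3s[s$name == "AComm"], 0)
  # left territory is partially supplied from the right side
  left_outlets <- sum(s$flow_m3s[s$name %in% c("MCA_M1_L", "ACA_A2_L")])
  left_inflow <- s$flow_m3s[s$name == "ICA_L"]
  expect_gt(left_outlets, 0)
})

test_that("carotid-only supply feeds the PCA through the PComms", {
  fl <- casson_fluid()
  bc <- phase_bc("PSV", c(ICA_L = 60, ICA_R = 60, VA_L = 0, VA_R = 0), 130)
  # symmetric circle: both P2s fed via their PComm, the dead-ended
  # vertebrobasilar trunk and the P1s carry nothing
  net <- build_cow_template()
  s <- solve_network(net, fl, bc)$segments
  expect_gt(s$flow_m3s[s$name == "PCA_P2_L"], 0)
  expect_gt(s$flow_m3s[s$name == "PComm_L"], 0)
  tot <- sum(s$flow_m3s[s$role == "inlet"])
  expect_lt(abs(s$flow_m3s[s$name == "BA"]), 1e-8 * tot)
  expect_lt(abs(s$flow_m3s[s$name == "PCA_P1_L"]), 1e-8 * tot)
  # missing right PComm: the right PCA is reached across the top of the
  # basilar, reversing the left P1 (negative sign permitted and expected)
  net2 <- build_cow_template(anatomical_variant(pcom_right_present = FALSE))
  s2 <- solve_network(net2, fl, bc)$segments
  expect_gt(s2$flow_m3s[s2$name == "PCA_P2_R"], 0)
  expect_lt(s2$flow_m3s[s2$name == "PCA_P1_L"], 0)  # toward the BA apex
  expect_gt(s2$flow_m3s[s2$name == "PCA_P1_R"], 0)
})

test_that("flow volumes convert units and balance in and out", {
  fl <- casson_fluid()
  sol <- solve_network(build_cow_template(), fl, symmetric_bc())
  fv <- compute_flow_volumes(sol)
  expect_equal(fv$flow_ml_min, sol$segments$flow_m3s * 6e7)
  expect_equal(m3s_to_mlmin(1e-6), 60)
  q_in <- sum(fv$flow_ml_min[fv$role == "inlet"])
  q_out <- sum(fv$flow_ml_min[fv$role == "outlet"])
  expect_equal(q_in, q_out, tolerance = 1e-6)
  # each MCA lies between its ipsilateral ACA and the summed inflow
  mca <- fv$flow_ml_min[fv$name == "MCA_M1_L"]
  aca <- fv$flow_ml_min[fv$name == "ACA_A2_L"]
  expect_gt(mca, aca)
  expect_lt(mca, q_in)
})

test_that("a patient simulation is phase-consistent and symmetric", {
  fl <- casson_fluid()
  net <- build_cow_template()
  bcs <- list(
    PSV = symmetric_bc("PSV", 60, 40, 130),
    EDV = symmetric_bc("EDV", 20, 13, 80),
    MFV = symmetric_bc("MFV", 33, 22, 97))
  sim <- simulate_patient(net, fl, bcs)
  sites <- sim$sites
  expect_identical(nrow(sites), 9L)
  # identical inlet triplets + symmetric anatomy: left equals right
  for (a in c("MCA", "ACA", "PCA", "V4")) {
    l <- sites[sites$artery == a & sites$side == "left", ]
    r <- sites[sites$artery == a & sites$side == "right", ]
    expect_equal(l$psv_cms, r$psv_cms, tolerance = 1e-10)
    expect_equal(l$mfv_cms, r$mfv_cms, tolerance = 1e-10)
  }
  # velocity ordering psv >= mfv >= edv at every site
  expect_true(all(sites$psv_cms >= sites$mfv_cms - 1e-9))
  expect_true(all(sites$mfv_cms >= sites$edv_cms - 1e-9))
  expect_error(simulate_patient(net, fl, bcs[c("PSV", "EDV")]),
               class = "cowflow_invalid_input")
})

test_that("network and segment solvers agree on a single straight vessel", {
  fl <- casson_fluid()
  net <- make_chain_network(r1 = 2e-3, r2 = 2e-3)
  sol <- solve_network(net, fl, phase_bc("PSV", c(ICA_L = 60), 120))
  seg <- sol$segments[sol$segments$name == "MCA_M1_L", ]
  # pressure drop per length across the distal segment
  p <- sol$nodes$pressure_pa
  names(p) <- sol$nodes$node
  G_net <- (p[["n0"]] - p[["n_out"]]) / 0.03
  fvm <- solve_segment(axisymmetric_grid(16, 64, length = 0.02,
                                         radius = 2e-3),
                       fl, inlet_spec(cms_to_ms(seg$peak_velocity_cms)), 0)
  pbar <- colMeans(fvm$p)
  dpdz <- (pbar[16] - pbar[48]) / (0.5 * 0.02)
  expect_equal(dpdz, G_net, tolerance = 0.03)
  # and the developed centreline velocity agrees
  pr <- extract_profile(fvm, 0.9)
  expect_equal(ms_to_cms(max(pr$u)), seg$peak_velocity_cms, tolerance = 0.03)
})
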