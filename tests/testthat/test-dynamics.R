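# Deterministic expression dynamics and steady-state computation.

test_that("derivatives implement the two-stage synthesis/decay cascade", {
  params <- estimateParameters(kpn_ratios())$params
  phi_R <- 0.2362

  # from an empty cell only synthesis acts on transcripts
  d0 <- stateDerivatives(systemState(), params, kpn_trans(), phi_R)
  expect_equal(unname(d0[1:3]),
               c(phi_R, activityM(params, 0), activityC(params, 0)))
  expect_equal(unname(d0[4:6]), c(0, 0, 0))

  # all six derivatives vanish at the analytic fixed point
  eq <- steadyState(params, kpn_trans())
  d_eq <- stateDerivatives(eq, params, kpn_trans(), phi_R = eq[["m_R"]])
  expect_lt(max(abs(d_eq)), 1e-8)

  # silent promoters and an empty cell stay empty
  off <- thermoParams(f = 1, g = 0.1, alpha_tilde = 0, beta = 0.5)
  d_off <- stateDerivatives(systemState(), off, kpn_trans(), phi_R = 0)
  expect_equal(max(abs(d_off)), 0)
})

test_that("analytic steady state satisfies the fixed-point identities", {
  params <- estimateParameters(kpn_ratios())$params
  trans <- kpn_trans()
  eq <- steadyState(params, trans)

  # independent bisection oracle for the equilibrium C level
  p_star <- oracle_steady_pC(params$f, params$g, params$alpha_tilde,
                             params$beta)
  expect_equal(eq[["p_C"]], p_star, tolerance = 1e-8)
  expect_equal(eq[["p_C"]], 4.252, tolerance = 1e-3)

  # transcripts equal activities, proteins are (k/x) times transcripts
  expect_equal(eq[["m_M"]], activityM(params, eq[["p_C"]]))
  expect_equal(eq[["m_C"]], activityC(params, eq[["p_C"]]))
  expect_equal(unname(eq[4:6]),
               unname((trans$k_tilde / trans$x) * eq[1:3]))

  # with the steady-state-equality parameters all proteins are ~ equal
  expect_lt(diff(range(eq[4:6])) / eq[["p_C"]], 0.01)

  # no roadblock: C protein accumulates, M is strongly repressed
  open <- thermoParams(params$f, params$g, params$alpha_tilde, 1)
  eq1 <- steadyState(open, trans)
  expect_equal(eq1[["p_C"]],
               oracle_steady_pC(params$f, params$g, params$alpha_tilde, 1),
               tolerance = 1e-8)
  expect_equal(eq1[["p_C"]], 9.744, tolerance = 1e-3)
  expect_equal(eq1[["p_M"]], 0.156, tolerance = 1e-2)

  # silent transcription gives the empty fixed point
  off <- thermoParams(f = 1, g = 0.1, alpha_tilde = 0, beta = 0.5)
  expect_equal(max(abs(steadyState(off, trans, phi_R = 0))), 0)
})

test_that("long-time integration converges to the analytic steady state", {
  params <- estimateParameters(kpn_ratios())$params
  traj <- simulateDynamics(params, kpn_trans())
  eq <- steadyState(params, kpn_trans())
  final <- unlist(traj[nrow(traj), -1])
  expect_equal(unname(final), unname(unclass(eq)), tolerance = 1e-6)
  expect_identical(unname(unlist(traj[1, -1])), rep(0, 6))
  expect_true(all(diff(traj$tau) > 0))
  expect_true(all(unlist(traj[-1]) >= 0))
})

test_that("a trajectory started at steady state stays there", {
  params <- estimateParameters(kpn_ratios())$params
  eq <- steadyState(params, kpn_trans())
  traj <- simulateDynamics(params, kpn_trans(), initial = eq,
                           tau_end = 20, extend = FALSE)
  for (col in c("m_M", "p_M", "p_C"))
    expect_equal(traj[[col]], rep(eq[[col]], nrow(traj)), tolerance = 1e-6)
})

test_that("clamped activities reduce transcripts to the linear closed form", {
  params <- estimateParameters(kpn_ratios())$params
  traj <- simulateDynamics(params, kpn_trans(), clamp_p_C = TRUE,
                           tau_end = 10, extend = FALSE, n_points = 101)
  phi <- activityM(params, 0)
  expect_equal(traj$m_M, phi * (1 - exp(-traj$tau)), tolerance = 1e-6)
})

test_that("wild-type methyltransferase overshoots before settling", {
  params <- estimateParameters(kpn_ratios())$params
  traj <- simulateDynamics(params, kpn_trans())
  m <- trajectoryMetrics(traj, "p_M")
  expect_gt(m$peak, m$final)
  expect_gt(m$overshoot_ratio, 2)
  expect_lt(m$peak_time, max(traj$tau) / 2)
})

test_that("trajectory metrics handle flat, rising and empty inputs", {
  flat <- structure(data.frame(tau = 0:10, m_R = 0, m_M = 0, m_C = 0,
                               p_R = 1, p_M = 2, p_C = 3),
                    class = c("trajectory", "data.frame"))
  expect_equal(trajectoryMetrics(flat, "p_M")$overshoot_ratio, 1)

  rising <- flat
  rising$p_M <- seq(0, 5, length.out = 11)
  mr <- trajectoryMetrics(rising, "p_M")
  expect_equal(mr$overshoot_ratio, 1)
  expect_equal(mr$peak_time, 10)

  zero <- flat
  zero$p_M <- 0
  expect_equal(trajectoryMetrics(zero, "p_M")$overshoot_ratio, 1)

  expect_error(trajectoryMetrics(flat[0, ], "p_M"), "non-empty")
})

test_that("integration matches the fixed point across random parameter sets", {
  for (i in 1:4) {
    params <- draw_params(i)
    eq <- steadyState(params, kpn_trans())
    traj <- simulateDynamics(params, kpn_trans())
    final <- unlist(traj[nrow(traj), -1])
    expect_equal(unname(final), unname(unclass(eq)), tolerance = 1e-6)
  }
})
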