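# Statistical-weight model of the shared M/C regulatory region.

test_that("configuration weights follow the five-configuration scheme", {
  params <- thermoParams(f = 2.9, g = 0.02, alpha_tilde = 28, beta = 0.44)

  # no C protein: tetramer configurations carry no weight
  w0 <- configurationWeights(params, 0)
  expect_identical(w0$w_empty, 1)
  expect_equal(w0$w_tetramer, 0)
  expect_equal(w0$w_RNAP_C_plus_tetramer, 0)
  expect_equal(occupancyProbabilities(params, 0)[["RNAP_M"]],
               2.9 / (1 + 2.9 + 0.02))

  # worked example at p_c = 1
  w1 <- configurationWeights(params, 1)
  expect_equal(unlist(w1), c(w_empty = 1, w_RNAP_M = 2.9, w_RNAP_C = 0.02,
                             w_tetramer = 1, w_RNAP_C_plus_tetramer = 0.02,
                             Z = 4.94))
  expect_equal(occupancyProbabilities(params, 1)[["RNAP_M"]], 2.9 / 4.94)

  # saturating C protein: tetramer-containing configurations dominate
  occ <- occupancyProbabilities(params, 1e6)
  expect_equal(occ[["tetramer"]] + occ[["RNAP_C_plus_tetramer"]], 1,
               tolerance = 1e-12)
})

test_that("occupancy probabilities sum to one for any valid input", {
  for (i in 1:5) {
    params <- draw_params(i)
    for (p_c in c(0, 0.3, 1, 4.25, 50, 1e5, 1e80)) {
      occ <- occupancyProbabilities(params, p_c)
      expect_equal(sum(occ), 1, tolerance = 1e-12)
      expect_true(all(occ >= 0))
    }
  }
})

test_that("M-promoter activity decreases with C level and matches partition sums", {
  params <- draw_params(1)
  grid <- c(0, 0.1, 0.5, 1, 2, 4, 8, 20, 100)
  act <- activityM(params, grid)
  expect_true(all(diff(act) < 0))
  expect_equal(activityM(params, 1e100), 0)

  # fold-repression equals the ratio of brute-force partition sums
  Z <- function(p) {
    sum(unlist(configurationWeights(params, p)[1:5]))
  }
  for (p in grid) {
    expect_equal(activityM(params, 0) / activityM(params, p), Z(p) / Z(0),
                 tolerance = 1e-12)
  }

  # no statistical weight on the M promoter means no M transcription
  none <- thermoParams(f = 0, g = 0.1, alpha_tilde = 12, beta = 0.5)
  expect_equal(activityM(none, grid), rep(0, length(grid)))
})

test_that("C initiation rate matches its closed form and vanishes at g = 0", {
  params <- draw_params(2)
  p <- c(0, 0.7, 3, 40)
  expect_equal(initiationRateC(params, p),
               oracle_init_C(params$f, params$g, params$alpha_tilde, p),
               tolerance = 1e-14)
  silent <- thermoParams(f = 2, g = 0, alpha_tilde = 10, beta = 0.3)
  expect_equal(initiationRateC(silent, p), rep(0, length(p)))
})

test_that("elongation completion probability is bounded and monotone", {
  for (i in 1:4) {
    params <- draw_params(i)
    grid <- c(0, 0.2, 1, 3, 10, 1e4, 1e80)
    pr <- elongationProbability(params, grid)
    expect_equal(pr[1], 1)                       # no roadblock bound at p_c = 0
    expect_true(all(pr >= params$beta - 1e-12 & pr <= 1 + 1e-12))
    expect_true(all(diff(pr) <= 1e-12))
    expect_equal(pr[length(grid)], params$beta, tolerance = 1e-6)
  }
  open <- thermoParams(f = 1, g = 0.1, alpha_tilde = 5, beta = 1)
  expect_equal(elongationProbability(open, c(0, 1, 100)), rep(1, 3))
})

test_that("effective C activity is initiation times completion", {
  params <- draw_params(3)
  p <- c(0, 0.5, 2, 4.25, 30)
  expect_equal(activityC(params, p),
               initiationRateC(params, p) * elongationProbability(params, p))
  # full read-through: roadblock has no effect on effective activity
  open <- thermoParams(params$f, params$g, params$alpha_tilde, 1)
  expect_identical(activityC(open, p), initiationRateC(open, p))
})

test_that("constitutive R activity is a validated constant", {
  expect_identical(activityR(0), 0)
  expect_identical(activityR(0.2362), 0.2362)
  expect_error(activityR(-1), "value")
  expect_error(activityR(NA_real_), "value")
})

test_that("domain errors are raised for invalid inputs", {
  params <- thermoParams(2.9, 0.02, 28, 0.44)
  expect_error(activityM(params, -1), "non-negative")
  expect_error(activityM(params, NaN), "finite")
  expect_error(thermoParams(2.9, 0.02, 28, 1.2), "beta")
  expect_error(thermoParams(-1, 0.02, 28, 0.4), "non-negative")
  expect_error(thermoParams(Inf, 0.02, 28, 0.4), "finite")
  expect_error(activityM(list(f = 1), 0), "thermo_params")
})

test_that("unrescaling restores absolute time and amounts", {
  traj <- structure(data.frame(tau = c(0, 1, 2), m_R = c(0, 1, 2),
                               m_M = 1:3, m_C = 0, p_R = 0, p_M = 2,
                               p_C = c(0, 4, 8)),
                    class = c("trajectory", "data.frame"))
  abs <- unrescaleTrajectory(traj, lambda_t = 0.5, h = 16)
  expect_equal(abs$time, c(0, 2, 4))
  expect_equal(abs$p_C, c(0, 8, 16))           # amounts scale by h^(1/4) = 2
})
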