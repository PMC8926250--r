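test_that("interaction range responds to uptake, diffusion and leakage as expected", {
  base <- matched_param_pair()$simple
  R0 <- interaction_range(base)
  expect_gt(R0, 0)

  # doubling the uptake rate shrinks the range; more diffusion extends it
  faster_uptake <- modifyList(base, list(r_u = 2 * base$r_u))
  class(faster_uptake) <- "molecular_params"
  expect_lt(interaction_range(faster_uptake), R0)
  faster_diff <- modifyList(base, list(D = 2 * base$D))
  class(faster_diff) <- "molecular_params"
  expect_gt(interaction_range(faster_diff), R0)

  # monotonicity over random parameter draws
  set.seed(41)
  for (i in 1:20) {
    p <- molecular_params(D = runif(1, 10, 1000), r_u = runif(1, 0.1, 50),
                          r_l = runif(1, 0, 20), rho = runif(1, 0.1, 0.9),
                          beta = runif(1, 0.5, 3), gamma = runif(1, 0.1, 5),
                          mu_wt = 1)
    p2 <- modifyList(p, list(r_u = p$r_u * 1.5))
    class(p2) <- "molecular_params"
    expect_lt(interaction_range(p2), interaction_range(p))
  }
})

test_that("vanishing leakage reduces the range log factor to ln 4", {
  pp <- matched_param_pair()
  p <- modifyList(pp$simple, list(r_l = 0))
  class(p) <- "molecular_params"
  pref <- p$beta / (2 * (1 - p$rho)) *
    sqrt(2 * p$D / (p$rho * (2 + p$rho) * p$r_u))
  expect_equal(interaction_range(p), pref * log(4), tolerance = 1e-12)
  # the limit is approached continuously from r_l > 0
  p_eps <- modifyList(p, list(r_l = 1e-10))
  class(p_eps) <- "molecular_params"
  expect_equal(interaction_range(p_eps), pref * log(4), tolerance = 1e-4)
})

test_that("maximum growth rate is bounded, increases with leakage and saturates", {
  pp <- matched_param_pair()
  p <- pp$simple
  expect_gte(max_growth_rate(p), 0)
  expect_lte(max_growth_rate(p), p$mu_wt)

  # no leakage, no cross-feeding growth
  p0 <- modifyList(p, list(r_l = 0))
  class(p0) <- "molecular_params"
  expect_identical(max_growth_rate(p0), 0)

  # saturating limit mu_hat -> mu_wt for large leakage ratio
  pbig <- modifyList(p, list(r_l = 1e9, gamma = 1))
  class(pbig) <- "molecular_params"
  expect_equal(max_growth_rate(pbig), p$mu_wt, tolerance = 1e-4)

  # monotone in r_l, bounded by mu_wt, over random draws
  set.seed(42)
  for (i in 1:20) {
    q <- molecular_params(D = 100, r_u = 1, r_l = runif(1, 0, 10),
                          rho = 0.5, beta = 1, gamma = runif(1, 0.1, 5),
                          mu_wt = runif(1, 0.1, 2))
    q2 <- modifyList(q, list(r_l = q$r_l + 1))
    class(q2) <- "molecular_params"
    expect_gt(max_growth_rate(q2), max_growth_rate(q))
    expect_lte(max_growth_rate(q2), q$mu_wt)
  }

  # leakage ratio 2: symbolic value 2 (sqrt(2) - 1), cross-checked against
  # the per-type form with theta = 2
  p2 <- molecular_params(D = 100, r_u = 1, r_l = 2, rho = 0.5, beta = 1,
                         gamma = 1, mu_wt = 1)
  expect_equal(max_growth_rate(p2), 2 * (sqrt(2) - 1), tolerance = 1e-12)
  a2 <- asymmetric_exchange_params(D = 100, rho = 0.5, beta = 1,
                                   r_u_p = 1, r_l_p = 2, r_u_n = 1,
                                   r_l_n = 2, I_C_p = 2, K_n = 1, mu_n = 1)
  expect_equal(theta_const(a2), 2, tolerance = 1e-12)
  expect_equal(max_growth_rate_general(a2), max_growth_rate(p2),
               tolerance = 1e-12)
})

test_that("per-type forms reduce to the equal-rate forms to machine precision", {
  set.seed(7)
  for (i in 1:25) {
    pp <- matched_param_pair(D = runif(1, 10, 2000), r_u = runif(1, 0.1, 50),
                             r_l = runif(1, 0.01, 20), rho = runif(1, 0.1, 0.9),
                             beta = runif(1, 0.5, 3), mu_wt = runif(1, 0.1, 2),
                             I_C = runif(1, 1, 50), K = runif(1, 0.1, 10))
    expect_equal(theta_const(pp$asym), pp$simple$r_l / pp$simple$gamma,
                 tolerance = 1e-14)
    expect_equal(delta_const(pp$asym), pp$simple$r_l / pp$simple$gamma,
                 tolerance = 1e-14)
    expect_equal(max_growth_rate_general(pp$asym), max_growth_rate(pp$simple),
                 tolerance = 1e-14)
    expect_equal(interaction_range_general(pp$asym),
                 interaction_range(pp$simple), tolerance = 1e-14)
  }
})

test_that("delta equals the product of its three factors computed independently", {
  a <- asymmetric_exchange_params(D = 500, rho = 0.6, beta = 1.1,
                                  r_u_p = 12, r_l_p = 3, r_u_n = 7,
                                  r_l_n = 1.5, I_C_p = 8, K_n = 2.5,
                                  mu_n = 0.9)
  leak_flux <- a$r_l_p * a$I_C_p / (2 * a$mu_n * a$K_n)
  len_n <- 1 / sqrt(a$r_u_n + a$r_l_n)
  len_p <- 1 / sqrt(a$r_u_p + a$r_l_p)
  diff_len <- len_n / ((len_n + len_p) / 2)
  uptake <- (a$r_u_n + a$r_l_n) / (a$r_u_p + a$r_l_p)
  expect_equal(delta_const(a), leak_flux * diff_len * uptake,
               tolerance = 1e-12)
  # zero production kills the leakage-flux factor
  a0 <- modifyList(a, list(I_C_p = 0))
  class(a0) <- "asymmetric_exchange_params"
  expect_identical(delta_const(a0), 0)
  expect_identical(max_growth_rate_general(a0), 0)
})

test_that("neighborhood sizes match Monte-Carlo geometry oracles", {
  expect_identical(neighborhood_size_2d(0, 3, 1, 0.3), 0)
  expect_identical(neighborhood_size_3d(0, 3, 1, 0.2), 0)

  set.seed(11)
  r2 <- neighborhood_size_2d(2, 3, 1, 0.3)
  expect_equal(r2, 8.055, tolerance = 1e-3)
  expect_equal(r2, mc_shell_area_2d(2, 3, 1) * 0.3, tolerance = 0.01)
  r3 <- neighborhood_size_3d(2, 3, 1, 0.2)
  expect_equal(r3, mc_shell_volume_3d(2, 3, 1) * 0.2, tolerance = 0.02)

  # one more geometry away from the reference point
  expect_equal(neighborhood_size_2d(1.2, 5, 2, 0.4),
               mc_shell_area_2d(1.2, 5, 2) * 0.4, tolerance = 0.01)
  expect_equal(neighborhood_size_3d(3.5, 4, 1.5, 0.15),
               mc_shell_volume_3d(3.5, 4, 1.5) * 0.15, tolerance = 0.02)
})

test_that("dimensionality matters: 3D counts outgrow 2D counts without bound", {
  # shell volume over shell area grows linearly in R for R >> cell size
  Rs <- c(5, 20, 100, 500)
  ratio <- neighborhood_size_3d(Rs, 3, 1, 1) / neighborhood_size_2d(Rs, 3, 1, 1)
  expect_true(all(diff(ratio) > 0))
  expect_gt(ratio[4] / ratio[1], 50)
  # sphere-volume limit for R >> l, w
  expect_equal(neighborhood_size_3d(1e4, 3, 1, 0.2) /
                 (4 / 3 * pi * 1e4^3 * 0.2), 1, tolerance = 1e-3)
})

test_that("local rules from biophysics order labels and record swaps", {
  pp <- matched_param_pair()
  rules <- local_rules_from_biophysics(pp$simple, pp$simple, dimension = 2)
  expect_equal(rules$r_A, rules$r_B)
  expect_equal(rules$mu_hat_A, rules$mu_hat_B)
  expect_false(rules$swapped)

  # a molecule with faster uptake has a shorter range: consumed by A it
  # should keep A the small-neighborhood type; swapping inputs flags a swap
  short <- modifyList(pp$simple, list(r_u = 10 * pp$simple$r_u))
  class(short) <- "molecular_params"
  r1 <- local_rules_from_biophysics(short, pp$simple, dimension = 2)
  r2 <- local_rules_from_biophysics(pp$simple, short, dimension = 2)
  expect_false(r1$swapped)
  expect_true(r2$swapped)
  expect_equal(r1$r_A, r2$r_A)
  expect_equal(r1$r_B, r2$r_B)
  expect_lte(r1$r_A, r1$r_B)

  # random draws always satisfy the local-rules invariants
  set.seed(13)
  for (i in 1:10) {
    mk <- function() {
      p <- matched_param_pair(D = runif(1, 50, 1000), r_u = runif(1, 1, 40),
                              r_l = runif(1, 0.1, 10), rho = runif(1, 0.2, 0.8),
                              mu_wt = runif(1, 0.2, 2))$simple
      p
    }
    rl <- local_rules_from_biophysics(mk(), mk(), dimension = sample(2:3, 1))
    expect_gte(rl$r_B, rl$r_A)
    expect_gte(rl$mu_hat_A, 0)
    expect_gte(rl$mu_hat_B, 0)
  }
})

test_that("invalid biophysical parameters are rejected", {
  expect_error(molecular_params(D = 100, r_u = 1, r_l = 1, rho = 1,
                                beta = 1, gamma = 1, mu_wt = 1),
               "rho")
  expect_error(molecular_params(D = 100, r_u = 1, r_l = 1, rho = 0.5,
                                beta = 1, gamma = 0, mu_wt = 1),
               "gamma")
  p <- matched_param_pair()$simple
  p$r_u <- 0
  p$r_l <- 0
  expect_error(interaction_range(p), "uptake and leakage")
})
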