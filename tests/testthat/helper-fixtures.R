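# Shared fixtures for the test suite. Everything is generated in code.

# molecular parameters with identical per-type rates plus the matched
# asymmetric parameterization (gamma = 2 mu K / I_C)
matched_param_pair <- function(D = 800, r_u = 20, r_l = 4, rho = 0.65,
                               beta = 1.2, mu_wt = 0.7, I_C = 10, K = 2) {
  gamma <- 2 * mu_wt * K / I_C
  list(
    simple = molecular_params(D = D, r_u = r_u, r_l = r_l, rho = rho,
                              beta = beta, gamma = gamma, mu_wt = mu_wt,
                              l = 3, w = 1, rho_2D = 0.3, rho_3D = 0.2),
    asym = asymmetric_exchange_params(D = D, rho = rho, beta = beta,
                                      r_u_p = r_u, r_l_p = r_l,
                                      r_u_n = r_u, r_l_n = r_l,
                                      I_C_p = I_C, K_n = K, mu_n = mu_wt,
                                      l = 3, w = 1, rho_2D = 0.3,
                                      rho_3D = 0.2))
}

# local rules matching the experimental cross-feeding community: the
# small-neighborhood slow type (r = 10) against the large-neighborhood fast
# type (r = 130), growth-rate ratio 0.22 / 0.78
experimental_rules <- function() local_rules(10, 130, 0.22, 0.78)

# a consistent pair state drawn from composition probabilities
random_pair_state <- function(rules, N = 1000) {
  p <- list(P_A = runif(1, 0.05, 0.95),
            P_BgA = runif(1, 0.05, 0.95),
            P_AgB = runif(1, 0.05, 0.95))
  links_from_probabilities(p, rules, N = N)
}

# Monte-Carlo area of the stadium-shaped shell of width R around a rod of
# length l, width w (2D); independent geometry oracle
mc_shell_area_2d <- function(R, l, w, n = 1e6) {
  half_seg <- (l - w) / 2
  bx <- half_seg + w / 2 + R
  by <- w / 2 + R
  x <- runif(n, -bx, bx)
  y <- runif(n, -by, by)
  # distance from point to the axis segment [-half_seg, half_seg] x {0}
  dx <- pmax(abs(x) - half_seg, 0)
  dist <- sqrt(dx^2 + y^2)
  inside <- dist > w / 2 & dist <= w / 2 + R
  mean(inside) * (2 * bx) * (2 * by)
}

# Monte-Carlo volume of the shell around a spherocylinder (3D)
mc_shell_volume_3d <- function(R, l, w, n = 1e6) {
  half_seg <- (l - w) / 2
  bx <- half_seg + w / 2 + R
  byz <- w / 2 + R
  x <- runif(n, -bx, bx)
  y <- runif(n, -byz, byz)
  z <- runif(n, -byz, byz)
  dx <- pmax(abs(x) - half_seg, 0)
  dist <- sqrt(dx^2 + y^2 + z^2)
  inside <- dist > w / 2 & dist <= w / 2 + R
  mean(inside) * (2 * bx) * (2 * byz) * (2 * byz)
}
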