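test_that("link counts and composition probabilities are mutually consistent", {
  rules <- local_rules(3, 3, 1, 1)
  # all-A state
  st <- pair_state(10, N_AA = 30, N_AB = 0, N_BA = 0, N_BB = 0)
  p <- probabilities_from_links(st, rules)
  expect_equal(p$P_A, 1)
  expect_equal(p$P_BgA, 0)
  expect_equal(p$P_AgB, 0)

  # two mutually linked cells of opposite type
  rules1 <- local_rules(1, 1, 1, 1)
  st2 <- pair_state(2, N_AA = 0, N_AB = 1, N_BA = 1, N_BB = 0)
  p2 <- probabilities_from_links(st2, rules1)
  expect_equal(unlist(p2), c(P_A = 0.5, P_BgA = 1, P_AgB = 1))

  # round trip probabilities -> links -> probabilities
  set.seed(3)
  for (i in 1:20) {
    r <- local_rules(sample(2:10, 1), sample(10:130, 1), runif(1), runif(1))
    st <- random_pair_state(r)
    p <- probabilities_from_links(st, r)
    st2 <- links_from_probabilities(p, r, N = st$N)
    expect_equal(unclass(st2), unclass(st), tolerance = 1e-12)
  }

  # violated out-degree regularity is an error
  bad <- pair_state(10, N_AA = 15, N_AB = 15, N_BA = 100, N_BB = 100)
  expect_error(probabilities_from_links(bad, rules), "regularity")
})

test_that("transition rates vanish at boundaries and balance under symmetry", {
  rules <- local_rules(5, 5, 1, 1)
  p_no_partner <- structure(list(P_A = 0.5, P_BgA = 0, P_AgB = 0.4),
                            class = "composition_probabilities")
  expect_equal(transition_rates(p_no_partner, rules)[["T_plus"]], 0)

  p_sym <- structure(list(P_A = 0.5, P_BgA = 0.3, P_AgB = 0.3),
                     class = "composition_probabilities")
  rt <- transition_rates(p_sym, rules)
  expect_equal(rt[["T_plus"]], rt[["T_minus"]], tolerance = 1e-12)

  # rates are built for the frequency-linear model only
  expect_error(
    transition_rates(p_sym, local_rules(5, 5, 1, 1, "density_linear")),
    "frequency-linear")
})

test_that("link-change vectors conserve out-degree regularity exactly", {
  set.seed(5)
  for (i in 1:20) {
    rules <- local_rules(sample(2:10, 1), sample(10:120, 1),
                         runif(1), runif(1))
    st <- random_pair_state(rules)
    p <- probabilities_from_links(st, rules)
    dl <- link_change_vectors(p, rules)
    # A replaces B: one more A focal (r_A in-links), one fewer B focal
    expect_equal(sum(dl$delta_plus[c("N_AA", "N_AB")]), rules$r_A,
                 tolerance = 1e-12)
    expect_equal(sum(dl$delta_plus[c("N_BA", "N_BB")]), -rules$r_B,
                 tolerance = 1e-12)
    expect_equal(sum(dl$delta_minus[c("N_AA", "N_AB")]), -rules$r_A,
                 tolerance = 1e-12)
    expect_equal(sum(dl$delta_minus[c("N_BA", "N_BB")]), rules$r_B,
                 tolerance = 1e-12)
    # equal degrees: total link count is conserved event by event
    if (rules$r_A == rules$r_B) {
      expect_equal(sum(dl$delta_plus), 0, tolerance = 1e-12)
      expect_equal(sum(dl$delta_minus), 0, tolerance = 1e-12)
    }
  }

  # near-boundary feasibility: applying one A-replaces-B event to an
  # all-B-except-one-A community keeps all link counts non-negative
  rules <- local_rules(4, 8, 1, 1)
  N <- 100
  p0 <- list(P_A = 1 / N, P_BgA = 1, P_AgB = 4 / (8 * (N - 1)))
  st <- links_from_probabilities(p0, rules, N = N)
  dl <- link_change_vectors(probabilities_from_links(st, rules), rules)
  after <- unlist(st[c("N_AA", "N_AB", "N_BA", "N_BB")]) + dl$delta_plus
  expect_true(all(after >= -1e-9))
})

test_that("the dynamics are stationary exactly at the closed-form equilibrium", {
  rules <- experimental_rules()
  PA <- as.numeric(steady_state_frequency(rules))
  eq <- list(P_A = PA,
             P_BgA = (1 - PA) * local_to_global_ratio(rules$r_A),
             P_AgB = PA * local_to_global_ratio(rules$r_B))
  st <- links_from_probabilities(eq, rules)
  d <- ode_rhs(st, rules)
  expect_lt(max(abs(d)), 1e-9)

  # absorbing states are fixed points
  for (pa in c(0, 1)) {
    st0 <- links_from_probabilities(list(P_A = pa, P_BgA = 0, P_AgB = 0),
                                    rules)
    expect_identical(max(abs(ode_rhs(st0, rules))), 0)
  }

  # relabeling symmetry: with symmetric rules a symmetric state has
  # dN_AA/dt = dN_BB/dt and dN_AB/dt = dN_BA/dt
  rs <- local_rules(6, 6, 0.8, 0.8)
  stS <- links_from_probabilities(list(P_A = 0.5, P_BgA = 0.31, P_AgB = 0.31),
                                  rs)
  dS <- ode_rhs(stS, rs)
  expect_equal(dS[["N_AA"]], dS[["N_BB"]], tolerance = 1e-12)
  expect_equal(dS[["N_AB"]], dS[["N_BA"]], tolerance = 1e-12)
})

test_that("integration converges to the unique interior equilibrium", {
  rules <- experimental_rules()
  PA_eq <- as.numeric(steady_state_frequency(rules))

  # starting at the equilibrium the trajectory stays there
  eq <- list(P_A = PA_eq,
             P_BgA = (1 - PA_eq) * local_to_global_ratio(rules$r_A),
             P_AgB = PA_eq * local_to_global_ratio(rules$r_B))
  tr <- pa_integrate(links_from_probabilities(eq, rules), rules, t_end = 50,
                     n_out = 11)
  expect_lt(max(abs(tr$P_A - PA_eq)), 1e-6)

  # symmetric rules pull any interior start to 0.5
  rs <- local_rules(8, 8, 1, 1)
  for (p0 in c(0.2, 0.7)) {
    st0 <- links_from_probabilities(list(P_A = p0, P_BgA = 1 - p0,
                                         P_AgB = p0), rs)
    tr <- pa_integrate(st0, rs, t_end = 2000, n_out = 21)
    expect_equal(tr$P_A[21], 0.5, tolerance = 1e-6)
  }

  # several starts all converge to the closed-form value
  for (p0 in c(0.1, 0.5, 0.9)) {
    res <- pa_equilibrium_ode(rules, init_freq_A = p0)
    expect_true(res$converged)
    expect_equal(res$P_A, PA_eq, tolerance = 1e-4)
  }
})

test_that("spatial equilibrium frequency reproduces its anchor values", {
  # experimental parameterization: the slow small-neighborhood type settles
  # at 0.20, against 0.22 well-mixed
  rules <- experimental_rules()
  expect_equal(round(as.numeric(steady_state_frequency(rules)), 2), 0.20)
  expect_equal(well_mixed_frequency(rules), 0.22, tolerance = 1e-12)

  # symmetry: equal rates give 0.5 for any common neighborhood size
  for (r in c(3, 10, 100))
    expect_equal(as.numeric(steady_state_frequency(local_rules(r, r, 1, 1))),
                 0.5)

  # collapse boundary: ratio 2 at r = 3 lands exactly on fixation of A
  b <- steady_state_frequency(local_rules(3, 3, 2, 1))
  expect_equal(as.numeric(b), 1)
  expect_identical(attr(b, "collapsed"), "A_fixed")

  expect_error(steady_state_frequency(local_rules(1.5, 3, 1, 1)), "r_A >= 2")
  expect_equal(well_mixed_frequency(local_rules(3, 3, 1, 3)), 0.25)
  expect_error(well_mixed_frequency(local_rules(3, 3, 0, 0)), "positive")
})

test_that("local-to-global ratio matches its closed form and limits", {
  expect_equal(local_to_global_ratio(3), 0.5)
  expect_equal(round(local_to_global_ratio(130), 2), 0.99)
  expect_equal(local_to_global_ratio(1e9), 1, tolerance = 1e-8)
  expect_error(local_to_global_ratio(1.5), ">= 2")
})

test_that("productivity is reduced by spatial structure and vanishes at collapse", {
  # experimental parameterization: spatial productivity is 0.92 of well-mixed
  eq <- productivity(experimental_rules())
  expect_equal(round(eq$productivity_ratio, 2), 0.92)
  expect_identical(eq$collapsed, "none")

  # symmetric small neighborhoods: the ratio equals the local-enrichment
  # factor (r - 2) / (r - 1) = 0.5 at r = 3
  eq_r3 <- productivity(local_rules(3, 3, 1, 1))
  expect_equal(eq_r3$productivity_ratio, 0.5, tolerance = 1e-12)

  # large neighborhoods recover the well-mixed productivity
  eqL <- productivity(local_rules(1e5, 1e5, 0.4, 1.1))
  expect_equal(eqL$productivity_ratio, 1, tolerance = 1e-4)

  # spatial productivity never exceeds well-mixed for cross-feeding
  set.seed(17)
  for (i in 1:20) {
    rl <- local_rules(runif(1, 2.2, 20), runif(1, 20, 130),
                      runif(1, 0.1, 1), runif(1, 0.1, 1))
    expect_lte(productivity(rl)$productivity_ratio, 1 + 1e-12)
  }

  # collapse: zero spatial productivity
  eqc <- productivity(local_rules(3, 3, 5, 1))
  expect_identical(eqc$collapsed, "A_fixed")
  expect_identical(eqc$productivity_spatial, 0)
})

test_that("coexistence interval matches algebra and a numerical scan", {
  expect_equal(collapse_interval(3, 3), c(lower = 0.5, upper = 2))
  # well-mixed limit: any ratio coexists
  ci_inf <- collapse_interval(1e6, 1e6)
  expect_lt(ci_inf[["lower"]], 1e-5)
  expect_gt(ci_inf[["upper"]], 1e5)

  # endpoints agree with the sign change of the unclamped equilibrium value
  for (r in list(c(3, 3), c(4, 30), c(10, 130))) {
    ci <- collapse_interval(r[1], r[2])
    for (edge in ci) {
      lo <- steady_state_frequency(
        local_rules(r[1], r[2], edge * 0.999, 1), unclamped = TRUE)
      hi <- steady_state_frequency(
        local_rules(r[1], r[2], edge * 1.001, 1), unclamped = TRUE)
      expect_true(lo > 0 && lo < 1 || hi > 0 && hi < 1)
      expect_false(lo > 0 && lo < 1 && hi > 0 && hi < 1)
    }
  }
})

test_that("generalized growth models reproduce their equilibrium criteria", {
  # density dependence: equal mu * r products balance the community
  pa <- steady_state_general(local_rules(5, 10, 2, 1, "density_linear"))
  expect_equal(pa$P_A, 0.5, tolerance = 1e-12)
  # the type with the larger product takes the majority
  pa2 <- steady_state_general(local_rules(5, 10, 3, 1, "density_linear"))
  expect_gt(pa2$P_A, 0.5)
  pa3 <- steady_state_general(local_rules(5, 10, 1, 1, "density_linear"))
  expect_lt(pa3$P_A, 0.5)

  # mutual inhibition: clustering shelters cells, so the spatial community
  # grows at least as fast as the well-mixed one
  for (r in c(3, 5, 8)) {
    inh <- steady_state_general(local_rules(r, r, 1, 1, "inhibition_linear"))
    expect_gte(inh$mean_growth_spatial, inh$mean_growth_wm - 1e-12)
  }

  # steady-state local structure follows the same local-to-global relation
  # under every growth model
  for (model in c("frequency_linear", "density_linear", "inhibition_linear")) {
    res <- steady_state_general(local_rules(6, 40, 0.9, 1.3, model))
    if (res$collapsed == "none") {
      expect_equal(res$P_BgA / (1 - res$P_A), local_to_global_ratio(6),
                   tolerance = 1e-12)
      expect_equal(res$P_AgB / res$P_A, local_to_global_ratio(40),
                   tolerance = 1e-12)
    }
  }

  # a custom linear frequency model recovers the closed forms
  rules_c <- local_rules(10, 130, 0.22, 0.78, "custom")
  res_c <- steady_state_general(rules_c,
                                growth_A = function(n) 0.22 * n / 10,
                                growth_B = function(n) 0.78 * n / 130)
  expect_equal(res_c$P_A,
               as.numeric(steady_state_frequency(experimental_rules())),
               tolerance = 1e-8)
  # and a custom density model recovers the density closed form
  rules_d <- local_rules(5, 10, 2, 1, "custom")
  res_d <- steady_state_general(rules_d,
                                growth_A = function(n) 2 * n,
                                growth_B = function(n) 1 * n)
  expect_equal(res_d$P_A, 0.5, tolerance = 1e-8)
})

test_that("relabeling the two types mirrors the equilibrium composition", {
  set.seed(23)
  for (i in 1:10) {
    r <- runif(1, 2.5, 40)
    muA <- runif(1, 0.2, 1)
    muB <- runif(1, 0.2, 1)
    p1 <- steady_state_frequency(local_rules(r, r, muA, muB),
                                 unclamped = TRUE)
    p2 <- steady_state_frequency(local_rules(r, r, muB, muA),
                                 unclamped = TRUE)
    expect_equal(p1, 1 - p2, tolerance = 1e-12)
  }
})
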