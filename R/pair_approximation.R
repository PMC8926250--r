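# Pair approximation on directed regular graphs for two cell types with
# different neighborhood sizes. State is the vector of directed link counts
# N_{X<-Y} ("focal X receives building blocks from neighbor Y"); the three
# independent dynamical variables are the global frequency P(A) and the two
# local partner frequencies P(B|A, r_A) and P(A|B, r_B).

#' Pair state: directed link counts
#'
#' @param N total number of cells (> 0).
#' @param N_AA,N_AB,N_BA,N_BB directed link counts (non-negative reals);
#'   `N_XY` counts X<-Y links, i.e. focal cells of type X receiving from
#'   neighbors of type Y.
#' @return An object of class `pair_state`.
#' @export
pair_state <- function(N, N_AA, N_AB, N_BA, N_BB) {
  .check_num(N, "N", strict = TRUE)
  for (nm in c("N_AA", "N_AB", "N_BA", "N_BB")) .check_num(get(nm), nm)
  structure(list(N = unname(N), N_AA = unname(N_AA), N_AB = unname(N_AB),
                 N_BA = unname(N_BA), N_BB = unname(N_BB)),
            class = "pair_state")
}

#' Composition probabilities from link counts
#'
#' Translates a [pair_state()] into the three dynamical variables of the
#' pair approximation: `P_A = (N_AA + N_AB) / (r_A N)`,
#' `P_BgA = N_AB / (N_AA + N_AB)` and `P_AgB = N_BA / (N_BA + N_BB)`.
#' A conditional frequency is defined as 0 when the focal type is absent.
#' The out-degree regularity invariant (`N_BA + N_BB = r_B N_B` with
#' `N_B = N - N_A`) is checked and an inconsistent state is an error.
#'
#' @param state a [pair_state()].
#' @param rules a [local_rules()] object.
#' @param tol relative tolerance for the regularity check.
#' @return A list with class `composition_probabilities` and elements
#'   `P_A`, `P_BgA`, `P_AgB`.
#' @export
probabilities_from_links <- function(state, rules, tol = 1e-6) {
  stopifnot(inherits(state, "pair_state"), inherits(rules, "local_rules"))
  in_A <- state$N_AA + state$N_AB
  in_B <- state$N_BA + state$N_BB
  N_A <- in_A / rules$r_A
  N_B <- state$N - N_A
  if (N_A > state$N * (1 + tol) || N_B < -tol * state$N)
    stop("inconsistent pair state: N_A exceeds N", call. = FALSE)
  if (abs(in_B - rules$r_B * N_B) > tol * max(1, rules$r_B * state$N))
    stop("inconsistent pair state: out-degree regularity violated",
         call. = FALSE)
  structure(list(P_A = .clamp(N_A / state$N),
                 P_BgA = if (in_A > 0) state$N_AB / in_A else 0,
                 P_AgB = if (in_B > 0) state$N_BA / in_B else 0),
            class = "composition_probabilities")
}

#' Link counts from composition probabilities
#'
#' Inverse of [probabilities_from_links()]: rebuilds a consistent
#' [pair_state()] from `(P_A, P_BgA, P_AgB)` for a community of `N` cells.
#'
#' @param probs a `composition_probabilities` list (or plain list with the
#'   same fields).
#' @param rules a [local_rules()] object.
#' @param N total number of cells.
#' @return A [pair_state()].
#' @export
links_from_probabilities <- function(probs, rules, N = 1) {
  N_A <- probs$P_A * N
  N_B <- N - N_A
  pair_state(N,
             N_AA = rules$r_A * N_A * (1 - probs$P_BgA),
             N_AB = rules$r_A * N_A * probs$P_BgA,
             N_BA = rules$r_B * N_B * probs$P_AgB,
             N_BB = rules$r_B * N_B * (1 - probs$P_AgB))
}

# Internal closure machinery ------------------------------------------------
#
# The two conditionals are measured over different windows (r_A for A focals,
# r_B for B focals), but the bookkeeping of a replacement event needs the
# neighborhood composition around one site evaluated at *both* window sizes.
# We translate across windows with a single community-wide clustering
# intensity: writing q_BA = P_B (1 - s_A/(r_A - 1)) and
# q_AB = P_A (1 - s_B/(r_B - 1)), the common intensity is the
# composition-weighted mean s = P_A s_B + P_B s_A, and the partner deficit in
# a window of size r is s/(r - 1). The deficit has this 1/(r - 1) form
# because exactly one neighbor slot of a focal cell is occupied by its
# kin-by-direct-descent (parent or offspring); the interior fixed point of
# the resulting dynamics is unique and reproduces the closed-form
# equilibrium composition and local structure.
.pa_cross_window <- function(probs, rules) {
  P_A <- probs$P_A
  P_B <- 1 - P_A
  r_A <- rules$r_A
  r_B <- rules$r_B
  s_A <- if (P_B > 0 && r_A > 1) (1 - probs$P_BgA / P_B) * (r_A - 1) else 0
  s_B <- if (P_A > 0 && r_B > 1) (1 - probs$P_AgB / P_A) * (r_B - 1) else 0
  s_bar <- P_A * s_B + P_B * s_A
  q_AB_rA <- if (r_A > 1) .clamp(P_A * (1 - s_bar / (r_A - 1))) else .clamp(P_A)
  q_BA_rB <- if (r_B > 1) .clamp(P_B * (1 - s_bar / (r_B - 1))) else .clamp(P_B)
  kappa <- if (probs$P_AgB > 0) q_AB_rA / probs$P_AgB else 1
  list(s_bar = s_bar, q_AB_rA = q_AB_rA, q_BA_rB = q_BA_rB, kappa = kappa)
}

#' Replacement event rates
#'
#' Rates of the two events that change the community composition under the
#' frequency-linear growth model: `T_plus`, a type A cell reproduces and
#' replaces a B neighbor, and `T_minus`, a type B cell reproduces and
#' replaces an A neighbor:
#' \deqn{T^+ = P(A)\, P(B|A)\,\frac{1 + P(B|A)(r_A-1)}{r_A}\,\hat\mu_A}
#' \deqn{T^- = P(B)\, P(A|B)\,\frac{1 + P(A|B)(r_B-1)}{r_B}\,\hat\mu_B\,\kappa}
#' where \eqn{\kappa} is the probability that an A neighbor found in B's
#' (larger) interaction neighborhood also lies in the smaller replication
#' neighborhood, computed with the cross-window closure (at the interior
#' equilibrium \eqn{\kappa} equals the ratio of the two local-enrichment
#' factors \eqn{(r_A-2)/(r_A-1)} and \eqn{(r_B-2)/(r_B-1)}).
#'
#' @param probs a `composition_probabilities` list.
#' @param rules a [local_rules()] with `growth_model = "frequency_linear"`.
#' @return Named numeric vector `c(T_plus, T_minus)`.
#' @export
transition_rates <- function(probs, rules) {
  stopifnot(inherits(rules, "local_rules"))
  if (rules$growth_model != "frequency_linear")
    stop("transition_rates() implements the frequency-linear model; ",
         "use steady_state_general() for other growth models", call. = FALSE)
  P_A <- probs$P_A
  P_B <- 1 - P_A
  q_BA <- probs$P_BgA
  q_AB <- probs$P_AgB
  cw <- .pa_cross_window(probs, rules)
  T_plus <- P_A * q_BA * (1 + q_BA * (rules$r_A - 1)) / rules$r_A *
    rules$mu_hat_A
  T_minus <- P_B * q_AB * (1 + q_AB * (rules$r_B - 1)) / rules$r_B *
    rules$mu_hat_B * cw$kappa
  c(T_plus = T_plus, T_minus = T_minus)
}

#' Expected link changes per replacement event
#'
#' Bookkeeping of one replacement event in the pair approximation. When an A
#' replaces a B (`delta_plus`): the replaced B loses its incoming links (one
#' guaranteed A parent plus `r_B - 1` neighbors typed by `P(A|B, r_B)`), the
#' new A gains `r_A` incoming links (parent plus `r_A - 1` neighbors typed
#' by the window-`r_A` composition around the site), and every focal cell
#' whose neighborhood contains the site has one incoming link re-typed.
#' `delta_minus` is the mirrored bookkeeping for a B replacing an A. The
#' vectors conserve out-degree regularity exactly: `delta_plus` increases
#' `N_AA + N_AB` by `r_A` and decreases `N_BA + N_BB` by `r_B`.
#'
#' @inheritParams transition_rates
#' @return List with numeric vectors `delta_plus` and `delta_minus`, each
#'   named `(N_AA, N_AB, N_BA, N_BB)`.
#' @export
link_change_vectors <- function(probs, rules) {
  stopifnot(inherits(rules, "local_rules"))
  r_A <- rules$r_A
  r_B <- rules$r_B
  q_BA <- probs$P_BgA
  q_AB <- probs$P_AgB
  cw <- .pa_cross_window(probs, rules)
  qABp <- cw$q_AB_rA   # A frequency in a window of size r_A around the site
  qBAp <- cw$q_BA_rB   # B frequency in a window of size r_B around the site
  delta_plus <- c(
    N_AA = 2 * (1 + (r_A - 1) * qABp),
    N_AB = (r_A - 1) * (1 - qABp) - (1 + (r_A - 1) * qABp),
    N_BA = -(1 + (r_B - 1) * q_AB) + (r_B - 1) * (1 - q_AB),
    N_BB = -2 * (r_B - 1) * (1 - q_AB)
  )
  delta_minus <- c(
    N_AA = -2 * (r_A - 1) * (1 - q_BA),
    N_AB = -(1 + (r_A - 1) * q_BA) + (r_A - 1) * (1 - q_BA),
    N_BA = (r_B - 1) * (1 - qBAp) - (1 + (r_B - 1) * qBAp),
    N_BB = 2 * (1 + (r_B - 1) * qBAp)
  )
  list(delta_plus = delta_plus, delta_minus = delta_minus)
}

#' Time derivative of the link counts
#'
#' Right-hand side of the link dynamics
#' \eqn{dN_{X\leftarrow Y}/dt = T^+ \Delta^+_{XY} + T^- \Delta^-_{XY}}
#' (scaled by the community size, which is constant). At an absorbing state
#' (`P_A` 0 or 1) all derivatives vanish. Only three of the four components
#' are independent: the out-degree regularity constraints are conserved
#' exactly by the event bookkeeping.
#'
#' @param state a [pair_state()].
#' @param rules a [local_rules()] object.
#' @return Named numeric vector of `d(N_AA, N_AB, N_BA, N_BB)/dt`.
#' @export
ode_rhs <- function(state, rules) {
  probs <- probabilities_from_links(state, rules)
  if (probs$P_A <= 0 || probs$P_A >= 1)
    return(c(N_AA = 0, N_AB = 0, N_BA = 0, N_BB = 0))
  rates <- transition_rates(probs, rules)
  dl <- link_change_vectors(probs, rules)
  state$N * (rates[["T_plus"]] * dl$delta_plus +
               rates[["T_minus"]] * dl$delta_minus)
}

# raw rhs on a numeric vector, for the integrator
.pa_rhs_vec <- function(y, rules, N = 1) {
  st <- pair_state(N, y[1], y[2], y[3], y[4])
  unname(ode_rhs(st, rules))
}

#' Integrate the pair-approximation dynamics
#'
#' Solves the link dynamics with an adaptive stiff-capable integrator
#' (`deSolve::ode`, `lsoda`) and reports the trajectory of the three
#' composition variables. When the growth-rate ratio lies inside the
#' coexistence interval the trajectory converges to the unique interior
#' equilibrium from any interior start; otherwise it approaches the
#' corresponding absorbing state.
#'
#' @param state0 initial [pair_state()], e.g. from
#'   [links_from_probabilities()]. A well-mixed start at frequency `p` is
#'   `links_from_probabilities(list(P_A = p, P_BgA = 1 - p, P_AgB = p),
#'   rules)`.
#' @param rules a [local_rules()] object (frequency-linear model).
#' @param t_end end time (units of `1/mu_hat`).
#' @param n_out number of reporting points (linearly spaced).
#' @param rtol,atol integrator tolerances.
#' @return A data frame with columns `time`, `P_A`, `P_BgA`, `P_AgB`.
#' @export
pa_integrate <- function(state0, rules, t_end, n_out = 201,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(state0, "pair_state"))
  y0 <- c(state0$N_AA, state0$N_AB, state0$N_BA, state0$N_BB)
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, parms)
                        list(.pa_rhs_vec(y, rules, state0$N)),
                      parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("pair-approximation integration failed; istate = ",
         attr(sol, "istate")[1], call. = FALSE)
  out <- data.frame(time = sol[, 1], P_A = NA_real_, P_BgA = NA_real_,
                    P_AgB = NA_real_)
  for (i in seq_len(nrow(sol))) {
    p <- probabilities_from_links(
      pair_state(state0$N, sol[i, 2], sol[i, 3], sol[i, 4], sol[i, 5]),
      rules, tol = 1e-4)
    out$P_A[i] <- p$P_A
    out$P_BgA[i] <- p$P_BgA
    out$P_AgB[i] <- p$P_AgB
  }
  out
}

#' Pair-approximation equilibrium by direct integration
#'
#' Integrates the link dynamics in doubling time chunks until the maximum
#' relative rate of change drops below `deriv_tol` per unit time (or the
#' composition hits an absorbing boundary). Used to verify that the dynamic
#' fixed point coincides with the closed-form equilibrium.
#'
#' @param rules a [local_rules()] object (frequency-linear model).
#' @param init_freq_A initial global frequency of A (well-mixed start).
#' @param deriv_tol equilibrium threshold on `max |dN/dt| / N`.
#' @param t_max give up after this much integration time.
#' @return List with `P_A`, `P_BgA`, `P_AgB`, `converged` (logical) and
#'   `collapsed` (one of "none", "A_fixed", "B_fixed").
#' @export
pa_equilibrium_ode <- function(rules, init_freq_A = 0.5, deriv_tol = 1e-9,
                               t_max = 1e8) {
  p0 <- list(P_A = init_freq_A, P_BgA = 1 - init_freq_A, P_AgB = init_freq_A)
  y <- links_from_probabilities(p0, rules)
  y <- c(y$N_AA, y$N_AB, y$N_BA, y$N_BB)
  t_chunk <- 1
  t_done <- 0
  repeat {
    sol <- deSolve::ode(y = y, times = c(0, t_chunk),
                        func = function(t, yy, parms)
                          list(.pa_rhs_vec(yy, rules)),
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), -1]
    t_done <- t_done + t_chunk
    t_chunk <- t_chunk * 2
    d <- .pa_rhs_vec(y, rules)
    probs <- probabilities_from_links(pair_state(1, y[1], y[2], y[3], y[4]),
                                      rules, tol = 1e-4)
    boundary <- probs$P_A < 1e-9 || probs$P_A > 1 - 1e-9
    if (max(abs(d)) < deriv_tol || boundary || t_done > t_max) {
      collapsed <- if (probs$P_A > 1 - 1e-6) "A_fixed"
        else if (probs$P_A < 1e-6) "B_fixed" else "none"
      return(list(P_A = probs$P_A, P_BgA = probs$P_BgA, P_AgB = probs$P_AgB,
                  converged = max(abs(d)) < deriv_tol || boundary,
                  collapsed = collapsed))
    }
  }
}

# Closed forms ---------------------------------------------------------------

#' Equilibrium global frequency of type A (spatial)
#'
#' Closed-form steady state of the pair approximation for the
#' frequency-linear growth model:
#' \deqn{P(A) = \frac{\hat\mu_A\frac{r_A-2}{r_A} +
#'   \left(\frac{\hat\mu_A}{r_A}-\frac{\hat\mu_B}{r_B}\right)}
#'   {\hat\mu_A\frac{r_A-2}{r_A} + \hat\mu_B\frac{r_B-2}{r_B}}}
#' The value is clamped to `[0, 1]`; when the unclamped value leaves the
#' open interval the community collapses to fixation of the corresponding
#' type, recorded in the `"collapsed"` attribute.
#'
#' @param rules a [local_rules()] with `r_A >= 2` and
#'   `growth_model = "frequency_linear"`.
#' @param unclamped if `TRUE` return the raw value of the expression.
#' @return The equilibrium frequency of A, with attribute `collapsed`
#'   (one of "none", "A_fixed", "B_fixed").
#' @export
steady_state_frequency <- function(rules, unclamped = FALSE) {
  stopifnot(inherits(rules, "local_rules"))
  if (rules$growth_model != "frequency_linear")
    stop("closed form applies to the frequency-linear model", call. = FALSE)
  if (rules$r_A < 2)
    stop("closed-form equilibrium requires r_A >= 2", call. = FALSE)
  muA <- rules$mu_hat_A
  muB <- rules$mu_hat_B
  rA <- rules$r_A
  rB <- rules$r_B
  num <- muA * (rA - 2) / rA + (muA / rA - muB / rB)
  den <- muA * (rA - 2) / rA + muB * (rB - 2) / rB
  if (den == 0) stop("degenerate rules: both equilibrium terms vanish",
                     call. = FALSE)
  raw <- num / den
  if (unclamped) return(raw)
  out <- .clamp(raw)
  attr(out, "collapsed") <- if (raw >= 1) "A_fixed"
    else if (raw <= 0) "B_fixed" else "none"
  out
}

#' Equilibrium frequency in a well-mixed system
#'
#' Large-neighborhood limit of [steady_state_frequency()]:
#' \eqn{P(A)_{WM} = \hat\mu_A / (\hat\mu_A + \hat\mu_B)}.
#'
#' @param rules a [local_rules()] with `mu_hat_A + mu_hat_B > 0`.
#' @return The well-mixed equilibrium frequency of A.
#' @export
well_mixed_frequency <- function(rules) {
  stopifnot(inherits(rules, "local_rules"))
  tot <- rules$mu_hat_A + rules$mu_hat_B
  if (tot <= 0)
    stop("at least one maximum growth rate must be positive", call. = FALSE)
  rules$mu_hat_A / tot
}

#' Steady-state ratio of local to global partner frequency
#'
#' At equilibrium the frequency of the partner type within a focal cell's
#' interaction neighborhood is reduced relative to its global frequency by
#' the factor \eqn{(r-2)/(r-1)}, where `r` is the focal type's neighborhood
#' size; the deficit arises because one neighbor slot is occupied by the
#' focal cell's own parent or offspring.
#'
#' @param r neighborhood size (>= 2; continuous values allowed).
#' @return The ratio `(r - 2) / (r - 1)` in `[0, 1)`.
#' @export
local_to_global_ratio <- function(r) {
  if (any(r < 2)) stop("'r' must be >= 2", call. = FALSE)
  (r - 2) / (r - 1)
}

#' Coexistence interval of the growth-rate ratio
#'
#' Open interval of \eqn{\hat\mu_A/\hat\mu_B} within which the spatial
#' equilibrium composition is strictly interior to (0, 1). Outside the
#' interval one type fixes and all cross-feeding growth ceases (community
#' collapse), even though the same community would coexist at any ratio in
#' a well-mixed environment.
#'
#' @param r_A,r_B neighborhood sizes (>= 2).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
collapse_interval <- function(r_A, r_B) {
  .check_num(r_A, "r_A", lower = 2)
  .check_num(r_B, "r_B", lower = r_A)
  c(lower = r_A / (r_B * (r_A - 1)),
    upper = r_A * (r_B - 1) / r_B)
}

#' Equilibrium community properties and productivity
#'
#' Evaluates the closed-form spatial equilibrium (composition and local
#' structure) and the community productivity, i.e. the population-average
#' birth rate
#' \deqn{P(A)\hat\mu_A P(B|A) + P(B)\hat\mu_B P(A|B)}
#' at the spatial equilibrium with the steady-state local frequencies, and
#' compares it with the same expression evaluated with global frequencies
#' at the well-mixed equilibrium. A collapsed community has zero spatial
#' productivity.
#'
#' @param rules a [local_rules()] with `growth_model = "frequency_linear"`
#'   and `r_A >= 2`.
#' @return An object of class `equilibrium_result`: a list with `P_A`,
#'   `P_BgA`, `P_AgB`, `productivity_spatial`, `productivity_wm`,
#'   `productivity_ratio` and `collapsed`.
#' @export
productivity <- function(rules) {
  P_A <- steady_state_frequency(rules)
  collapsed <- attr(P_A, "collapsed")
  P_A <- as.numeric(P_A)
  P_B <- 1 - P_A
  cA <- local_to_global_ratio(rules$r_A)
  cB <- local_to_global_ratio(rules$r_B)
  P_BgA <- .clamp(P_B * cA)
  P_AgB <- .clamp(P_A * cB)
  sp <- if (collapsed != "none") 0 else
    P_A * rules$mu_hat_A * P_BgA + P_B * rules$mu_hat_B * P_AgB
  Pw <- well_mixed_frequency(rules)
  wm <- Pw * rules$mu_hat_A * (1 - Pw) + (1 - Pw) * rules$mu_hat_B * Pw
  structure(list(P_A = P_A, P_BgA = P_BgA, P_AgB = P_AgB,
                 productivity_spatial = sp, productivity_wm = wm,
                 productivity_ratio = if (wm > 0) sp / wm else NA_real_,
                 collapsed = collapsed),
            class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Pair-approximation equilibrium\n")
  cat(sprintf("  P(A) = %.4f  P(B|A) = %.4f  P(A|B) = %.4f\n",
              x$P_A, x$P_BgA, x$P_AgB))
  cat(sprintf("  productivity: spatial %.4f, well-mixed %.4f (ratio %.3f)\n",
              x$productivity_spatial, x$productivity_wm,
              x$productivity_ratio))
  if (x$collapsed != "none")
    cat("  community collapsed:", x$collapsed, "\n")
  invisible(x)
}

# Generalized growth models ---------------------------------------------------

# expected event rates at composition P_A, with steady-state local structure,
# for arbitrary growth functions g(n) of the partner count n in a window of
# (rounded) size r.
.general_rates <- function(P_A, rules, growth_A, growth_B) {
  rA <- round(rules$r_A)
  rB <- round(rules$r_B)
  cA <- local_to_global_ratio(rules$r_A)
  cB <- local_to_global_ratio(rules$r_B)
  qBA <- .clamp((1 - P_A) * cA)
  qAB <- .clamp(P_A * cB)
  kappa <- if (cB > 0) cA / cB else 1
  nA <- 0:rA
  nB <- 0:rB
  Tp <- P_A * sum(dbinom(nA, rA, qBA) * growth_A(nA) * nA / rA)
  Tm <- (1 - P_A) * sum(dbinom(nB, rB, qAB) * growth_B(nB) * nB / rB) * kappa
  c(T_plus = Tp, T_minus = Tm)
}

.builtin_growth <- function(model, mu, r) {
  switch(model,
         frequency_linear = function(n) mu * n / r,
         density_linear = function(n) mu * n,
         inhibition_linear = function(n) mu * (1 - n / r),
         stop("unknown growth model: ", model, call. = FALSE))
}

#' Equilibrium for generalized growth models
#'
#' Steady state of the pair approximation when the growth rate of a cell is
#' not proportional to the partner frequency. Built-in models:
#' `"frequency_linear"` (growth `mu * n / r`, closed form of
#' [steady_state_frequency()]), `"density_linear"` (growth `mu * n`, i.e.
#' proportional to the partner *count*, with `mu` the rate gained per
#' partner neighbor; the type with the larger `mu * r` product reaches the
#' majority), and `"inhibition_linear"` (growth `mu * (1 - n / r)`,
#' mutual growth inhibition). For `growth_model = "custom"`, supply growth
#' functions mapping a partner count vector to non-negative rates; the
#' fixed point is then located by root finding on `P_A`. The steady-state
#' relation between local and global composition
#' ([local_to_global_ratio()]) holds for every growth model and is used for
#' the local frequencies.
#'
#' @param rules a [local_rules()] object; its `growth_model` selects the
#'   model.
#' @param growth_A,growth_B for `"custom"` only: functions of the partner
#'   count `n` (vectorized) returning growth rates for A and B focal cells.
#' @return A list with `P_A`, `P_BgA`, `P_AgB`, `collapsed`,
#'   `mean_growth_spatial` and `mean_growth_wm` (the latter is the mean
#'   growth rate of the equivalent well-mixed community at its own
#'   equilibrium).
#' @export
steady_state_general <- function(rules, growth_A = NULL, growth_B = NULL) {
  stopifnot(inherits(rules, "local_rules"))
  if (rules$r_A < 2)
    stop("equilibria require r_A >= 2", call. = FALSE)
  muA <- rules$mu_hat_A
  muB <- rules$mu_hat_B
  rA <- rules$r_A
  rB <- rules$r_B
  cA <- local_to_global_ratio(rA)
  cB <- local_to_global_ratio(rB)
  model <- rules$growth_model

  raw <- switch(model,
    frequency_linear = steady_state_frequency(rules, unclamped = TRUE),
    density_linear = {
      den <- muA * (rA - 2) + muB * (rB - 2)
      if (den == 0) stop("degenerate density-model rules", call. = FALSE)
      (muA * (rA - 1) - muB) / den
    },
    inhibition_linear = {
      a <- muA * (rA - 1) / rA
      b <- muB * (rB - 1) / rB
      if (a * cA + b * cB == 0) stop("degenerate inhibition-model rules",
                                     call. = FALSE)
      (b - a * (1 - cA)) / (a * cA + b * cB)
    },
    custom = {
      if (!is.function(growth_A) || !is.function(growth_B))
        stop("custom model requires growth_A and growth_B functions",
             call. = FALSE)
      .root_custom(rules, growth_A, growth_B)
    })

  P_A <- .clamp(raw)
  collapsed <- if (raw >= 1) "A_fixed" else if (raw <= 0) "B_fixed" else "none"
  P_B <- 1 - P_A
  q_BA <- .clamp(P_B * cA)
  q_AB <- .clamp(P_A * cB)

  gA <- if (model == "custom") growth_A else .builtin_growth(model, muA, rA)
  gB <- if (model == "custom") growth_B else .builtin_growth(model, muB, rB)
  rAi <- round(rA)
  rBi <- round(rB)
  mg_sp <- if (collapsed != "none" && model != "inhibition_linear") 0 else
    P_A * sum(dbinom(0:rAi, rAi, q_BA) * gA(0:rAi)) +
    P_B * sum(dbinom(0:rBi, rBi, q_AB) * gB(0:rBi))
  mg_wm <- .wm_mean_growth(rules, gA, gB)

  list(P_A = P_A, P_BgA = q_BA, P_AgB = q_AB, collapsed = collapsed,
       mean_growth_spatial = mg_sp, mean_growth_wm = mg_wm)
}

# well-mixed reference: equilibrium of the same growth model with local
# frequencies equal to global ones, then the mean growth rate there.
.wm_mean_growth <- function(rules, gA, gB) {
  muA <- rules$mu_hat_A
  muB <- rules$mu_hat_B
  rA <- round(rules$r_A)
  rB <- round(rules$r_B)
  Pw <- switch(rules$growth_model,
    frequency_linear = muA / (muA + muB),
    inhibition_linear = muB / (muA + muB),
    density_linear = {
      # selection gradient is constant in a well-mixed density model:
      # the type with the larger mu * r product sweeps.
      d <- muA * rA - muB * rB
      if (d > 0) 1 else if (d < 0) 0 else 0.5
    },
    custom = {
      f <- function(p) {
        qA <- .clamp(1 - p)
        qB <- .clamp(p)
        p * sum(dbinom(0:rA, rA, qA) * gA(0:rA) * (0:rA) / rA) -
          (1 - p) * sum(dbinom(0:rB, rB, qB) * gB(0:rB) * (0:rB) / rB)
      }
      .bracket_root(f)
    })
  Pw * sum(dbinom(0:rA, rA, .clamp(1 - Pw)) * gA(0:rA)) +
    (1 - Pw) * sum(dbinom(0:rB, rB, .clamp(Pw)) * gB(0:rB))
}

.root_custom <- function(rules, growth_A, growth_B) {
  f <- function(p) {
    r <- .general_rates(p, rules, growth_A, growth_B)
    r[["T_plus"]] - r[["T_minus"]]
  }
  .bracket_root(f)
}

# locate a root of f on (eps, 1 - eps); among sign-change brackets prefer the
# one containing 0.5 (the solution reachable from a 50:50 start), otherwise
# the one closest to 0.5. Without a sign change, return the boundary with
# the smaller |f| (fixation).
.bracket_root <- function(f, eps = 1e-9, n_grid = 1001) {
  grid <- seq(eps, 1 - eps, length.out = n_grid)
  vals <- vapply(grid, f, numeric(1))
  sc <- which(vals[-length(vals)] * vals[-1] <= 0 &
                is.finite(vals[-length(vals)]) & is.finite(vals[-1]))
  if (length(sc) == 0)
    return(if (vals[1] > 0) 1 else 0)
  mid <- (grid[sc] + grid[sc + 1]) / 2
  pick <- sc[which.min(abs(mid - 0.5))]
  contains_half <- sc[grid[sc] <= 0.5 & grid[sc + 1] >= 0.5]
  if (length(contains_half) > 0) pick <- contains_half[1]
  uniroot(f, c(grid[pick], grid[pick + 1]), tol = 1e-12)$root
}
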