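# Biophysical layer: from molecular exchange parameters to local interaction
# rules (interaction range R, neighborhood size r, maximum growth rate mu_hat).

.check_num <- function(x, name, lower = 0, strict = FALSE, upper = Inf,
                       upper_strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (upper_strict && x >= upper)
    stop(sprintf("'%s' must be < %g", name, upper), call. = FALSE)
  if (!upper_strict && x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

#' Molecular parameters of one exchanged metabolite
#'
#' Bundles the biophysical rates and cell geometry that determine the local
#' interaction rules for one exchange direction, in the case where uptake and
#' leakage rates differ between molecules but not between cell types. All
#' quantities are interpreted in a single user-chosen time unit and length
#' unit; no internal conversion is performed.
#'
#' @param D diffusion coefficient of the molecule (length^2/time).
#' @param r_u active uptake rate (1/time).
#' @param r_l passive leakage rate (1/time).
#' @param rho volume fraction occupied by cells, in `[0, 1)`.
#' @param beta dimensionless calibration constant of the range formula. There
#'   is no hidden default: the value must be supplied explicitly.
#' @param gamma composite rate constant such that `r_l / gamma` is the
#'   dimensionless leakage ratio. It equals `2 * mu_wt * K / I_C`, where `K`
#'   is the Monod constant of the consumer and `I_C` the internal
#'   concentration of the molecule in producers; it is stored here directly
#'   in its composite form.
#' @param mu_wt growth rate of a non-auxotrophic wild-type cell when the
#'   molecule is externally supplied at saturation (1/time).
#' @param l,w average cell length and width (length); `l >= w > 0`. Optional,
#'   only needed to compute neighborhood sizes.
#' @param rho_2D areal cell density (cells/length^2), optional.
#' @param rho_3D volumetric cell density (cells/length^3), optional.
#'
#' @return An object of class `molecular_params`.
#' @seealso [interaction_range()], [max_growth_rate()],
#'   [local_rules_from_biophysics()]
#' @export
molecular_params <- function(D, r_u, r_l, rho, beta, gamma, mu_wt,
                             l = NA_real_, w = NA_real_,
                             rho_2D = NA_real_, rho_3D = NA_real_) {
  .check_num(D, "D")
  .check_num(r_u, "r_u")
  .check_num(r_l, "r_l")
  .check_num(rho, "rho", lower = 0, upper = 1, upper_strict = TRUE)
  .check_num(beta, "beta", strict = TRUE)
  .check_num(gamma, "gamma", strict = TRUE)
  .check_num(mu_wt, "mu_wt")
  if (!is.na(l) || !is.na(w)) {
    .check_num(w, "w", strict = TRUE)
    .check_num(l, "l", lower = w)
  }
  if (!is.na(rho_2D)) .check_num(rho_2D, "rho_2D")
  if (!is.na(rho_3D)) .check_num(rho_3D, "rho_3D")
  structure(list(D = D, r_u = r_u, r_l = r_l, rho = rho, beta = beta,
                 gamma = gamma, mu_wt = mu_wt, l = l, w = w,
                 rho_2D = rho_2D, rho_3D = rho_3D),
            class = "molecular_params")
}

#' Per-type exchange parameters for one exchanged molecule
#'
#' Generalization of [molecular_params()] to the case where uptake and
#' leakage rates differ between the producer and the non-producer
#' (= consumer) of the molecule, e.g. because the two types use different
#' transporters or differ in membrane permeability.
#'
#' @param D,rho,beta as in [molecular_params()].
#' @param r_u_p,r_l_p uptake and leakage rates of the producing type (1/time).
#' @param r_u_n,r_l_n uptake and leakage rates of the non-producing type
#'   (1/time).
#' @param I_C_p internal concentration of the molecule in producer cells.
#' @param K_n Monod constant of the consumer (> 0, concentration).
#' @param mu_n maximal growth rate of the consumer with the molecule in
#'   excess (> 0, 1/time).
#' @param l,w,rho_2D,rho_3D cell geometry and densities, as in
#'   [molecular_params()].
#'
#' @return An object of class `asymmetric_exchange_params`.
#' @seealso [interaction_range_general()], [max_growth_rate_general()]
#' @export
asymmetric_exchange_params <- function(D, rho, beta,
                                       r_u_p, r_l_p, r_u_n, r_l_n,
                                       I_C_p, K_n, mu_n,
                                       l = NA_real_, w = NA_real_,
                                       rho_2D = NA_real_, rho_3D = NA_real_) {
  .check_num(D, "D")
  .check_num(rho, "rho", lower = 0, upper = 1, upper_strict = TRUE)
  .check_num(beta, "beta", strict = TRUE)
  for (nm in c("r_u_p", "r_l_p", "r_u_n", "r_l_n"))
    .check_num(get(nm), nm)
  .check_num(I_C_p, "I_C_p")
  .check_num(K_n, "K_n", strict = TRUE)
  .check_num(mu_n, "mu_n", strict = TRUE)
  if (!is.na(l) || !is.na(w)) {
    .check_num(w, "w", strict = TRUE)
    .check_num(l, "l", lower = w)
  }
  structure(list(D = D, rho = rho, beta = beta,
                 r_u_p = r_u_p, r_l_p = r_l_p, r_u_n = r_u_n, r_l_n = r_l_n,
                 I_C_p = I_C_p, K_n = K_n, mu_n = mu_n,
                 l = l, w = w, rho_2D = rho_2D, rho_3D = rho_3D),
            class = "asymmetric_exchange_params")
}

# shared pieces -------------------------------------------------------------

# log-argument of the range formula: x (1 + sqrt(1 + 4/x)) + 4, continuous
# at x = 0 where it tends to 4.
.range_log_arg <- function(x) {
  if (x == 0) return(4)
  x * (1 + sqrt(1 + 4 / x)) + 4
}

# prefactor beta / (2 (1 - rho)) * sqrt(2 D / (rho (2 + rho) r_sum))
.range_prefactor <- function(beta, rho, D, r_sum) {
  if (r_sum <= 0)
    stop("sum of uptake and leakage rates must be > 0", call. = FALSE)
  if (rho <= 0)
    stop("'rho' must be > 0 to compute an interaction range", call. = FALSE)
  beta / (2 * (1 - rho)) * sqrt(2 * D / (rho * (2 + rho) * r_sum))
}

# saturating factor x (sqrt(1 + 2/x) - 1), computed in the algebraically
# equivalent form 2 / (sqrt(1 + 2/x) + 1) which is stable for x -> 0 and
# x -> Inf; bounded in [0, 1], monotone increasing in x.
.sat_factor <- function(x) {
  if (x == 0) return(0)
  2 / (sqrt(1 + 2 / x) + 1)
}

# operations ----------------------------------------------------------------

#' Interaction range from molecular parameters
#'
#' Distance over which the exchanged molecule effectively couples the growth
#' of two cells:
#' \deqn{R = \frac{\beta}{2(1-\rho)}
#'   \sqrt{\frac{2D}{\rho(2+\rho)(r_u+r_l)}}
#'   \ln\!\left[\frac{r_l}{\gamma}\left(1+\sqrt{1+\frac{4\gamma}{r_l}}\right)
#'   + 4\right]}
#' The range grows with the diffusion coefficient and shrinks with the
#' uptake rate; in the limit of vanishing leakage the logarithm tends to
#' \eqn{\ln 4}.
#'
#' @param params a [molecular_params()] object with `r_u + r_l > 0`.
#' @return The interaction range (length units of the input).
#' @export
interaction_range <- function(params) {
  stopifnot(inherits(params, "molecular_params"))
  pref <- .range_prefactor(params$beta, params$rho, params$D,
                           params$r_u + params$r_l)
  R <- pref * log(.range_log_arg(params$r_l / params$gamma))
  if (!is.finite(R))
    stop("interaction range is not finite for these parameters", call. = FALSE)
  R
}

#' Interaction range with per-type rates
#'
#' Generalized range formula in which the dimensionless leakage ratio is
#' replaced by the constant \eqn{\delta}: the product of the relative leakage
#' flux of producers, the relative diffusion length scale in consumer
#' regions, and the relative effective uptake rate of consumers:
#' \deqn{\delta = \frac{r_l^p I_C^p}{2\mu_n K_n}\cdot
#'   \frac{2\sqrt{r_u^p+r_l^p}}{\sqrt{r_u^n+r_l^n}+\sqrt{r_u^p+r_l^p}}\cdot
#'   \frac{r_u^n+r_l^n}{r_u^p+r_l^p}}
#' When producer and non-producer rates are identical, \eqn{\delta} reduces
#' to \eqn{r_l/\gamma} and the result equals [interaction_range()].
#'
#' @param params an [asymmetric_exchange_params()] object.
#' @return The interaction (growth) range.
#' @export
interaction_range_general <- function(params) {
  stopifnot(inherits(params, "asymmetric_exchange_params"))
  sum_n <- params$r_u_n + params$r_l_n
  sum_p <- params$r_u_p + params$r_l_p
  if (sum_p <= 0)
    stop("producer uptake + leakage rate must be > 0", call. = FALSE)
  pref <- .range_prefactor(params$beta, params$rho, params$D, sum_n)
  R <- pref * log(.range_log_arg(delta_const(params)))
  if (!is.finite(R))
    stop("interaction range is not finite for these parameters", call. = FALSE)
  R
}

#' @rdname interaction_range_general
#' @details `delta_const()` returns the constant \eqn{\delta} itself, the
#'   product of its three factors.
#' @export
delta_const <- function(params) {
  stopifnot(inherits(params, "asymmetric_exchange_params"))
  sum_n <- params$r_u_n + params$r_l_n
  sum_p <- params$r_u_p + params$r_l_p
  leak_flux <- params$r_l_p * params$I_C_p / (2 * params$mu_n * params$K_n)
  diff_len <- 2 * sqrt(sum_p) / (sqrt(sum_n) + sqrt(sum_p))
  upt <- sum_n / sum_p
  leak_flux * diff_len * upt
}

#' Maximum cross-feeding growth rate from molecular parameters
#'
#' Growth rate a cell attains when its entire interaction neighborhood is
#' the partner type:
#' \deqn{\hat\mu = \mu_{wt}\,\frac{r_l}{\gamma}
#'   \left(\sqrt{1+\frac{2\gamma}{r_l}}-1\right)}
#' bounded in \eqn{[0, \mu_{wt}]}, zero without leakage, and saturating at
#' the wild-type rate for large leakage ratios.
#'
#' @param params a [molecular_params()] object (`gamma > 0`).
#' @return The maximum growth rate (1/time).
#' @export
max_growth_rate <- function(params) {
  stopifnot(inherits(params, "molecular_params"))
  params$mu_wt * .sat_factor(params$r_l / params$gamma)
}

#' Maximum growth rate with per-type rates
#'
#' Generalization of [max_growth_rate()] in which the leakage ratio is
#' replaced by
#' \deqn{\theta = \frac{r_l^p I_C^p}{2\mu_n K_n}\cdot
#'   \frac{r_u^n+r_l^n}{r_u^p+r_l^p}}
#' giving \eqn{\mu_{max} = \mu_n\,\theta(\sqrt{1+2/\theta}-1)}. With
#' identical per-type rates \eqn{\theta = r_l/\gamma} and the simple form is
#' recovered.
#'
#' @param params an [asymmetric_exchange_params()] object.
#' @return The maximum growth rate of the consumer (1/time).
#' @export
max_growth_rate_general <- function(params) {
  stopifnot(inherits(params, "asymmetric_exchange_params"))
  params$mu_n * .sat_factor(theta_const(params))
}

#' @rdname max_growth_rate_general
#' @details `theta_const()` returns the constant \eqn{\theta} itself.
#' @export
theta_const <- function(params) {
  stopifnot(inherits(params, "asymmetric_exchange_params"))
  sum_p <- params$r_u_p + params$r_l_p
  if (sum_p <= 0)
    stop("producer uptake + leakage rate must be > 0", call. = FALSE)
  params$r_l_p * params$I_C_p / (2 * params$mu_n * params$K_n) *
    (params$r_u_n + params$r_l_n) / sum_p
}

#' Neighborhood size in two dimensions
#'
#' Number of cells within interaction range `R` of a rod-shaped focal cell
#' growing in a monolayer. The accessible region is the stadium-shaped shell
#' of width `R` around a rod of length `l` and width `w`:
#' \deqn{r = \left[2R(l-w) + \pi\left(R+\tfrac{w}{2}\right)^2 -
#'   \pi\left(\tfrac{w}{2}\right)^2\right]\rho_{2D}}
#' The continuous value is returned; rounding to an integer neighbor count
#' is deliberately left to the caller (the closed-form community equations
#' are smooth in `r`, and only the lattice simulator needs integers).
#'
#' @param R interaction range (length, >= 0).
#' @param l,w cell length and width (length, `l >= w > 0`).
#' @param rho_2D areal cell density (cells/length^2).
#' @return Expected number of neighbors (continuous).
#' @export
neighborhood_size_2d <- function(R, l, w, rho_2D) {
  if (!is.numeric(R) || any(R < 0)) stop("'R' must be >= 0", call. = FALSE)
  .check_num(w, "w", strict = TRUE)
  .check_num(l, "l", lower = w)
  .check_num(rho_2D, "rho_2D")
  (2 * R * (l - w) + pi * ((R + w / 2)^2 - (w / 2)^2)) * rho_2D
}

#' Neighborhood size in three dimensions
#'
#' Three-dimensional analog of [neighborhood_size_2d()]: the volume of the
#' shell of width `R` around a spherocylindrical cell (cylinder length
#' `l - w`, diameter `w`) times the volumetric cell density,
#' \deqn{r = \left[\pi\left(R+\tfrac{w}{2}\right)^2 (l-w) +
#'   \tfrac{4}{3}\pi\left(R+\tfrac{w}{2}\right)^3 -
#'   \pi\left(\tfrac{w}{2}\right)^2 (l-w) -
#'   \tfrac{4}{3}\pi\left(\tfrac{w}{2}\right)^3\right]\rho_{3D}}
#' For `R` much larger than the cell this scales as \eqn{R^3}, so for a
#' fixed range cells in 3D have many more neighbors than in 2D.
#'
#' @param R interaction range (length, >= 0).
#' @param l,w cell length and width (length, `l >= w > 0`).
#' @param rho_3D volumetric cell density (cells/length^3).
#' @return Expected number of neighbors (continuous).
#' @export
neighborhood_size_3d <- function(R, l, w, rho_3D) {
  if (!is.numeric(R) || any(R < 0)) stop("'R' must be >= 0", call. = FALSE)
  .check_num(w, "w", strict = TRUE)
  .check_num(l, "l", lower = w)
  .check_num(rho_3D, "rho_3D")
  a <- R + w / 2
  b <- w / 2
  (pi * (a^2 - b^2) * (l - w) + 4 / 3 * pi * (a^3 - b^3)) * rho_3D
}

#' Local interaction rules
#'
#' The four-number interface between the biophysical layer and the
#' community layer: the neighborhood sizes and the maximum growth rates of
#' the two types, plus the choice of growth model. By convention type B is
#' the type with the larger neighborhood (`r_B >= r_A`).
#'
#' @param r_A,r_B neighborhood sizes (>= 1, `r_B >= r_A`). May be
#'   non-integer; the closed-form equilibria treat `r` as continuous.
#' @param mu_hat_A,mu_hat_B maximum growth rates (1/time, >= 0).
#' @param growth_model one of `"frequency_linear"` (growth proportional to
#'   the partner frequency in the neighborhood), `"density_linear"` (growth
#'   proportional to the partner count), `"inhibition_linear"` (growth
#'   decreasing linearly with partner frequency), or `"custom"`.
#' @param swapped logical; `TRUE` when the A/B labels were exchanged to
#'   enforce `r_B >= r_A` (see [local_rules_from_biophysics()]).
#' @return An object of class `local_rules`.
#' @export
local_rules <- function(r_A, r_B, mu_hat_A, mu_hat_B,
                        growth_model = c("frequency_linear", "density_linear",
                                         "inhibition_linear", "custom"),
                        swapped = FALSE) {
  growth_model <- match.arg(growth_model)
  .check_num(r_A, "r_A", lower = 1)
  .check_num(r_B, "r_B", lower = r_A)
  .check_num(mu_hat_A, "mu_hat_A")
  .check_num(mu_hat_B, "mu_hat_B")
  stopifnot(is.logical(swapped), length(swapped) == 1L)
  structure(list(r_A = r_A, r_B = r_B,
                 mu_hat_A = mu_hat_A, mu_hat_B = mu_hat_B,
                 growth_model = growth_model, swapped = swapped),
            class = "local_rules")
}

#' @export
print.local_rules <- function(x, ...) {
  cat("Local interaction rules (", x$growth_model, ")\n", sep = "")
  cat(sprintf("  type A: r = %g, mu_hat = %g\n", x$r_A, x$mu_hat_A))
  cat(sprintf("  type B: r = %g, mu_hat = %g\n", x$r_B, x$mu_hat_B))
  if (isTRUE(x$swapped))
    cat("  (labels swapped so that r_B >= r_A)\n")
  invisible(x)
}

#' Local rules from molecular parameters
#'
#' Composes [interaction_range()] (or its per-type generalization),
#' [neighborhood_size_2d()]/[neighborhood_size_3d()] and
#' [max_growth_rate()] for each exchanged molecule into a [local_rules()]
#' object. `params_A` describes the molecule *consumed by type A*, i.e. it
#' sets A's interaction range and maximum growth rate; likewise `params_B`
#' for type B. If the resulting neighborhood of A is larger than that of B,
#' the labels are exchanged and the swap is recorded in the `swapped` field.
#'
#' @param params_A,params_B [molecular_params()] or
#'   [asymmetric_exchange_params()] objects describing the molecule each
#'   type consumes (cell geometry and density fields must be set).
#' @param dimension 2 for monolayers, 3 for three-dimensional structures.
#' @return A [local_rules()] object with attribute `ranges` holding the two
#'   interaction ranges (named after the final labels).
#' @export
local_rules_from_biophysics <- function(params_A, params_B, dimension = 2) {
  stopifnot(dimension %in% c(2, 3))
  one <- function(p) {
    if (inherits(p, "molecular_params")) {
      R <- interaction_range(p)
      mu <- max_growth_rate(p)
    } else if (inherits(p, "asymmetric_exchange_params")) {
      R <- interaction_range_general(p)
      mu <- max_growth_rate_general(p)
    } else {
      stop("parameters must be molecular_params or asymmetric_exchange_params",
           call. = FALSE)
    }
    r <- if (dimension == 2) {
      if (is.na(p$rho_2D)) stop("'rho_2D' is required in 2D", call. = FALSE)
      neighborhood_size_2d(R, p$l, p$w, p$rho_2D)
    } else {
      if (is.na(p$rho_3D)) stop("'rho_3D' is required in 3D", call. = FALSE)
      neighborhood_size_3d(R, p$l, p$w, p$rho_3D)
    }
    list(R = R, r = r, mu = mu)
  }
  a <- one(params_A)
  b <- one(params_B)
  swapped <- a$r > b$r
  if (swapped) {
    tmp <- a
    a <- b
    b <- tmp
  }
  out <- local_rules(r_A = a$r, r_B = b$r,
                     mu_hat_A = a$mu, mu_hat_B = b$mu,
                     growth_model = "frequency_linear", swapped = swapped)
  attr(out, "ranges") <- c(R_A = a$R, R_B = b$R)
  out
}
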