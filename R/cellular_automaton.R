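# R interface to the lattice simulator. Grids are integer matrices with
# 1 = type A and 2 = type B; boundaries are periodic.

#' Extended Moore neighborhood offsets
#'
#' All lattice offsets `(i, j)` with Chebyshev distance
#' `max(|i|, |j|) <= d`, excluding the origin; there are
#' `(2 d + 1)^2 - 1` of them (8 for `d = 1`, 120 for `d = 5`).
#'
#' @param d neighborhood range (integer >= 0).
#' @return Integer matrix with columns `i`, `j`, one row per offset.
#' @export
moore_offsets <- function(d) {
  .check_num(d, "d")
  d <- as.integer(d)
  if (d == 0L) return(matrix(integer(0), ncol = 2,
                             dimnames = list(NULL, c("i", "j"))))
  g <- expand.grid(i = -d:d, j = -d:d)
  g <- g[!(g$i == 0 & g$j == 0), , drop = FALSE]
  as.matrix(g[, c("i", "j")])
}

#' Cellular automaton configuration
#'
#' @param d_A,d_B extended Moore interaction ranges of types A and B
#'   (integers >= 1); the corresponding neighborhood sizes are
#'   `(2 d + 1)^2 - 1`.
#' @param mu_hat_A,mu_hat_B maximum growth rates.
#' @param height,width lattice dimensions (default 100 x 100).
#' @param d_R replication range: offspring replace a uniformly chosen
#'   neighbor within this range. Defaults to `min(d_A, d_B)`, mirroring the
#'   assumption that the replication neighborhood equals the smaller
#'   interaction neighborhood.
#' @param growth_model growth model, as in [local_rules()] (no custom model
#'   on the lattice).
#' @param init_freq_A initial frequency of A; sites are drawn independently.
#' @param seed RNG seed for [ca_run()].
#' @param n_events number of replacement events to simulate.
#' @return An object of class `ca_config`.
#' @export
ca_config <- function(d_A, d_B, mu_hat_A, mu_hat_B,
                      height = 100, width = 100, d_R = min(d_A, d_B),
                      growth_model = c("frequency_linear", "density_linear",
                                       "inhibition_linear"),
                      init_freq_A = 0.5, seed = 1L, n_events = 100000) {
  growth_model <- match.arg(growth_model)
  for (nm in c("d_A", "d_B", "d_R"))
    .check_num(get(nm), nm, lower = 1)
  .check_num(height, "height", lower = 3)
  .check_num(width, "width", lower = 3)
  .check_num(mu_hat_A, "mu_hat_A")
  .check_num(mu_hat_B, "mu_hat_B")
  .check_num(init_freq_A, "init_freq_A", lower = 0, upper = 1)
  .check_num(n_events, "n_events", lower = 0)
  if (2 * max(d_A, d_B) + 1 > min(height, width))
    stop("lattice too small for the interaction ranges: need ",
         "2 * max(d_A, d_B) + 1 <= min(height, width)", call. = FALSE)
  structure(list(d_A = as.integer(d_A), d_B = as.integer(d_B),
                 d_R = as.integer(d_R),
                 mu_hat_A = mu_hat_A, mu_hat_B = mu_hat_B,
                 height = as.integer(height), width = as.integer(width),
                 periodic = TRUE, growth_model = growth_model,
                 init_freq_A = init_freq_A, seed = as.integer(seed),
                 n_events = as.integer(n_events)),
            class = "ca_config")
}

#' @export
print.ca_config <- function(x, ...) {
  cat(sprintf("CA config: %dx%d periodic lattice, d_A=%d d_B=%d d_R=%d\n",
              x$height, x$width, x$d_A, x$d_B, x$d_R))
  cat(sprintf("  mu_hat_A=%g mu_hat_B=%g model=%s init P(A)=%g events=%d\n",
              x$mu_hat_A, x$mu_hat_B, x$growth_model, x$init_freq_A,
              x$n_events))
  invisible(x)
}

.model_code <- function(model) {
  match(model, c("frequency_linear", "density_linear",
                 "inhibition_linear")) - 1L
}

.check_grid <- function(grid) {
  if (!is.matrix(grid) || !all(grid %in% c(1L, 2L)))
    stop("a lattice snapshot must be an integer matrix of 1s (A) and 2s (B)",
         call. = FALSE)
  storage.mode(grid) <- "integer"
  grid
}

#' Random initial lattice
#'
#' @param height,width lattice dimensions.
#' @param freq_A per-site probability of type A (independent draws).
#' @return Integer matrix of 1s and 2s.
#' @export
lattice_random <- function(height, width, freq_A = 0.5) {
  matrix(ifelse(runif(height * width) < freq_A, 1L, 2L), height, width)
}

#' Growth rate of one lattice cell
#'
#' Growth rate of the cell at `pos` given the current snapshot: for the
#' frequency-linear model `mu_hat * partners / r` with `partners` the number
#' of opposite-type cells within the focal cell's own interaction range and
#' `r` its neighborhood size; `mu_hat * partners` for the density model and
#' `mu_hat * (1 - partners / r)` for mutual inhibition. A cross-feeding
#' cell with no partners in range cannot grow.
#'
#' @param grid integer matrix snapshot (1 = A, 2 = B).
#' @param pos integer vector `c(row, col)`.
#' @param config a [ca_config()].
#' @return The growth rate (1/time).
#' @export
cell_growth_rate <- function(grid, pos, config) {
  grid <- .check_grid(grid)
  stopifnot(length(pos) == 2, all(pos >= 1),
            pos[1] <= nrow(grid), pos[2] <= ncol(grid))
  t <- grid[pos[1], pos[2]]
  d <- if (t == 1L) config$d_A else config$d_B
  mu <- if (t == 1L) config$mu_hat_A else config$mu_hat_B
  off <- moore_offsets(d)
  rows <- ((pos[1] - 1 + off[, "i"]) %% nrow(grid)) + 1
  cols <- ((pos[2] - 1 + off[, "j"]) %% ncol(grid)) + 1
  partners <- sum(grid[cbind(rows, cols)] != t)
  r <- nrow(off)
  switch(config$growth_model,
         frequency_linear = mu * partners / r,
         density_linear = mu * partners,
         inhibition_linear = mu * (1 - partners / r))
}

#' Advance a lattice by replacement events
#'
#' Runs `n_events` replacement events on an explicit snapshot using the
#' current RNG state (call `set.seed()` beforehand for reproducibility).
#' Useful for stepping small configurations under test; [ca_run()] is the
#' front end for full simulations.
#'
#' @param grid integer matrix snapshot (1 = A, 2 = B).
#' @param config a [ca_config()] (its dimensions are taken from `grid`).
#' @param n_events number of events to attempt (default 1).
#' @return List with `grid` (the updated snapshot), `events_done`, and
#'   `absorbed` (`TRUE` when the total growth rate hit zero and the state
#'   is absorbing).
#' @export
ca_step <- function(grid, config, n_events = 1) {
  grid <- .check_grid(grid)
  res <- .ca_engine(grid, config$d_A, config$d_B, config$d_R,
                    config$mu_hat_A, config$mu_hat_B,
                    .model_code(config$growth_model),
                    as.integer(n_events), integer(0))
  list(grid = res$grid, events_done = res$events_done,
       absorbed = res$absorbed)
}

#' Run one cellular automaton simulation
#'
#' Initializes a random lattice from `config$seed` and simulates
#' `config$n_events` replacement events, recording the global composition,
#' the mean local partner frequencies of both types (each measured over its
#' own interaction range) and the community mean growth rate on a
#' log-spaced event grid. Identical configurations and seeds give
#' bit-identical trajectories.
#'
#' @param config a [ca_config()].
#' @param sample_points optional integer vector of event counts at which to
#'   record observables; defaults to ~120 log-spaced points plus the final
#'   event.
#' @param init_grid optional explicit starting snapshot (overrides the
#'   random initialization; the seed then only drives the dynamics).
#' @return An object of class `ca_run`: list with `config`, `trajectory`
#'   (data frame: `event`, `P_A`, `P_BgA`, `P_AgB`, `mean_growth`),
#'   `final_grid`, `final_P_A`, `events_done` and `absorbed`.
#' @export
ca_run <- function(config, sample_points = NULL, init_grid = NULL) {
  stopifnot(inherits(config, "ca_config"))
  set.seed(config$seed)
  grid <- if (is.null(init_grid))
    lattice_random(config$height, config$width, config$init_freq_A)
  else .check_grid(init_grid)
  if (is.null(sample_points)) {
    sample_points <- unique(c(
      round(10^seq(0, log10(max(1, config$n_events)), length.out = 120)),
      config$n_events))
    sample_points <- sample_points[sample_points >= 1]
  }
  sample_points <- as.integer(sort(unique(sample_points)))
  res <- .ca_engine(grid, config$d_A, config$d_B, config$d_R,
                    config$mu_hat_A, config$mu_hat_B,
                    .model_code(config$growth_model),
                    config$n_events, sample_points)
  traj <- data.frame(event = res$event, P_A = res$P_A, P_BgA = res$P_BgA,
                     P_AgB = res$P_AgB, mean_growth = res$mean_growth)
  traj <- traj[!is.na(traj$event), , drop = FALSE]
  structure(list(config = config, trajectory = traj,
                 final_grid = res$grid, final_P_A = res$final_P_A,
                 events_done = res$events_done, absorbed = res$absorbed),
            class = "ca_run")
}

#' @export
print.ca_run <- function(x, ...) {
  cat(sprintf("CA run: %d events (%s), final P(A) = %.4f\n",
              x$events_done,
              if (x$absorbed) "absorbed" else "completed",
              x$final_P_A))
  invisible(x)
}

#' Replicated cellular automaton runs
#'
#' Runs `n_replicates` independent simulations (distinct seeds) and
#' summarizes the final observables with normal-approximation 95%
#' confidence intervals.
#'
#' @param config a [ca_config()]; its `seed` seeds the first replicate when
#'   `seeds` is not given.
#' @param n_replicates number of replicates (>= 2).
#' @param seeds optional integer vector of seeds, length `n_replicates`.
#' @return An object of class `ca_ensemble`: list with `replicates` (data
#'   frame of per-replicate final observables), `summary` (data frame with
#'   `observable`, `mean`, `sd`, `ci_lower`, `ci_upper`) and `n_absorbed`.
#' @export
ca_ensemble <- function(config, n_replicates = 20, seeds = NULL) {
  stopifnot(inherits(config, "ca_config"), n_replicates >= 2)
  if (is.null(seeds))
    seeds <- config$seed + seq_len(n_replicates) - 1L
  stopifnot(length(seeds) == n_replicates)
  rows <- vector("list", n_replicates)
  for (k in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[k])
    run <- ca_run(cfg)
    tr <- run$trajectory
    last <- tr[nrow(tr), ]
    rows[[k]] <- data.frame(replicate = k, seed = seeds[k],
                            P_A = run$final_P_A,
                            P_BgA = last$P_BgA, P_AgB = last$P_AgB,
                            mean_growth = last$mean_growth,
                            absorbed = run$absorbed)
  }
  reps <- do.call(rbind, rows)
  summarize <- function(v) {
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    half <- stats::qnorm(0.975) * s / sqrt(sum(!is.na(v)))
    c(mean = m, sd = s, ci_lower = m - half, ci_upper = m + half)
  }
  obs <- c("P_A", "P_BgA", "P_AgB", "mean_growth")
  smry <- do.call(rbind, lapply(obs, function(o) {
    st <- summarize(reps[[o]])
    data.frame(observable = o, mean = st[["mean"]], sd = st[["sd"]],
               ci_lower = st[["ci_lower"]], ci_upper = st[["ci_upper"]])
  }))
  structure(list(replicates = reps, summary = smry,
                 n_absorbed = sum(reps$absorbed)),
            class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat(sprintf("CA ensemble: %d replicates (%d absorbed)\n",
              nrow(x$replicates), x$n_absorbed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
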