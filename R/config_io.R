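# Configuration loading/validation, tabular writers and the end-to-end
# molecules -> local rules -> equilibrium -> simulation pipeline.

.known_top <- c("units", "local_rules", "molecule_A", "molecule_B",
                "geometry", "ca", "pipeline")

#' Load and validate a configuration file
#'
#' Reads a YAML configuration and validates it against the package's domain
#' types. A configuration must contain a `units` block (declaring the time
#' and length units in which all rates and lengths are interpreted; no
#' conversion is performed) and either a `local_rules` block or a pair of
#' `molecule_A`/`molecule_B` blocks plus a `geometry` block. Unknown
#' top-level keys and unknown keys inside a block are rejected, and every
#' violated invariant is reported with its key path.
#'
#' Blocks:
#' \describe{
#'   \item{units}{`time`, `length` (free-text unit names).}
#'   \item{local_rules}{`r_A`, `r_B`, `mu_hat_A`, `mu_hat_B`, optional
#'     `growth_model`.}
#'   \item{molecule_A / molecule_B}{fields of [molecular_params()] (or of
#'     [asymmetric_exchange_params()] when per-type rates are given);
#'     `molecule_X` is the molecule consumed by type X.}
#'   \item{geometry}{`l`, `w`, `dimension`, and `rho_2D` or `rho_3D`.}
#'   \item{ca}{fields of [ca_config()] except the rates/ranges, which come
#'     from the rules.}
#'   \item{pipeline}{`n_replicates`, `seed`.}
#' }
#'
#' @param path path to a YAML file.
#' @return A validated parameter bundle of class `paircomm_config`: list
#'   with `units`, and `rules` and/or `molecules`, `ca`, `pipeline`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), .known_top)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$units) || is.null(raw$units$time) ||
        is.null(raw$units$length))
    stop("config requires a 'units' block with 'time' and 'length'",
         call. = FALSE)

  out <- list(units = raw$units)

  has_rules <- !is.null(raw$local_rules)
  has_mol <- !is.null(raw$molecule_A) || !is.null(raw$molecule_B)
  if (!has_rules && !has_mol)
    stop("config needs 'local_rules' or 'molecule_A'/'molecule_B' blocks",
         call. = FALSE)

  if (has_rules) {
    lr <- raw$local_rules
    allowed <- c("r_A", "r_B", "mu_hat_A", "mu_hat_B", "growth_model")
    unknown <- setdiff(names(lr), allowed)
    if (length(unknown) > 0)
      stop("unknown keys in local_rules: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out$rules <- tryCatch(
      local_rules(lr$r_A, lr$r_B, lr$mu_hat_A, lr$mu_hat_B,
                  growth_model = lr$growth_model %||% "frequency_linear"),
      error = function(e)
        stop("local_rules: ", conditionMessage(e), call. = FALSE))
  }

  if (has_mol) {
    if (is.null(raw$molecule_A) || is.null(raw$molecule_B) ||
          is.null(raw$geometry))
      stop("molecular input requires 'molecule_A', 'molecule_B' and ",
           "'geometry' blocks", call. = FALSE)
    geo <- raw$geometry
    allowed <- c("l", "w", "dimension", "rho_2D", "rho_3D")
    unknown <- setdiff(names(geo), allowed)
    if (length(unknown) > 0)
      stop("unknown keys in geometry: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    dimension <- geo$dimension %||% 2
    build <- function(block, label) {
      simple <- c("D", "r_u", "r_l", "rho", "beta", "gamma", "mu_wt")
      asym <- c("D", "rho", "beta", "r_u_p", "r_l_p", "r_u_n", "r_l_n",
                "I_C_p", "K_n", "mu_n")
      nm <- names(block)
      geo_args <- list(l = geo$l, w = geo$w,
                       rho_2D = geo$rho_2D %||% NA_real_,
                       rho_3D = geo$rho_3D %||% NA_real_)
      if (all(nm %in% simple) && all(simple %in% nm)) {
        do.call(molecular_params, c(block, geo_args))
      } else if (all(nm %in% asym) && all(asym %in% nm)) {
        do.call(asymmetric_exchange_params, c(block, geo_args))
      } else {
        stop(label, ": keys must be exactly {",
             paste(simple, collapse = ", "), "} or {",
             paste(asym, collapse = ", "), "}", call. = FALSE)
      }
    }
    out$molecules <- list(A = build(raw$molecule_A, "molecule_A"),
                          B = build(raw$molecule_B, "molecule_B"),
                          dimension = dimension)
  }

  if (!is.null(raw$ca)) {
    allowed <- c("height", "width", "d_A", "d_B", "d_R", "init_freq_A",
                 "seed", "n_events")
    unknown <- setdiff(names(raw$ca), allowed)
    if (length(unknown) > 0)
      stop("unknown keys in ca: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out$ca <- raw$ca
  }
  if (!is.null(raw$pipeline)) {
    allowed <- c("n_replicates", "seed")
    unknown <- setdiff(names(raw$pipeline), allowed)
    if (length(unknown) > 0)
      stop("unknown keys in pipeline: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    out$pipeline <- raw$pipeline
  }
  structure(out, class = "paircomm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a configuration bundle back to YAML
#'
#' Round-trip companion of [load_config()]: `dump_config(load_config(x))`
#' loads back to an identical bundle.
#'
#' @param config a `paircomm_config` bundle.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "paircomm_config"))
  raw <- list(units = config$units)
  if (!is.null(config$rules)) {
    r <- config$rules
    raw$local_rules <- list(r_A = r$r_A, r_B = r$r_B,
                            mu_hat_A = r$mu_hat_A, mu_hat_B = r$mu_hat_B,
                            growth_model = r$growth_model)
  }
  if (!is.null(config$molecules)) {
    strip <- function(p) {
      x <- unclass(p)
      x[c("l", "w", "rho_2D", "rho_3D")] <- NULL
      x
    }
    raw$molecule_A <- strip(config$molecules$A)
    raw$molecule_B <- strip(config$molecules$B)
    geo <- list(l = config$molecules$A$l, w = config$molecules$A$w,
                dimension = config$molecules$dimension)
    if (!is.na(config$molecules$A$rho_2D)) geo$rho_2D <- config$molecules$A$rho_2D
    if (!is.na(config$molecules$A$rho_3D)) geo$rho_3D <- config$molecules$A$rho_3D
    raw$geometry <- geo
  }
  if (!is.null(config$ca)) raw$ca <- config$ca
  if (!is.null(config$pipeline)) raw$pipeline <- config$pipeline
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Write a TSV with a manifest comment header
#'
#' Plain-text tabular output: comment lines (`# key: value`) carrying the
#' run provenance, then a tab-separated table with a header row.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param manifest named list written into the comment header.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, manifest = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(manifest))
    writeLines(sprintf("# %s: %s", nm, manifest[[nm]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full molecules-to-community pipeline
#'
#' Executes, in one invocation: the biophysical stage (when molecular
#' parameters are configured) deriving the local rules; the
#' pair-approximation equilibrium and productivity; a replicated cellular
#' automaton ensemble (when a `ca` block is configured); and a comparison
#' table of pair-approximation versus simulation per observable. Stage
#' outputs are written as TSV files under `out_dir`, and a manifest
#' recording the configuration echo, seeds, package version and per-stage
#' output paths is returned (and written as YAML). Every stochastic output
#' is regenerable from the seeds recorded in the manifest.
#'
#' @param config a `paircomm_config` bundle from [load_config()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed governing the simulation stage; overrides the
#'   config seed when given.
#' @param n_replicates CA replicates; overrides the config value when given.
#' @param quiet suppress stage messages.
#' @return The manifest, invisibly: list with `stages` (completed stage
#'   names), `outputs` (paths), `seeds`, `version`, `started`.
#' @export
pipeline <- function(config, out_dir = ".", seed = NULL, n_replicates = NULL,
                     quiet = FALSE) {
  stopifnot(inherits(config, "paircomm_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   version = as.character(utils::packageVersion("paircomm")),
                   stages = character(0), outputs = list(), seeds = list())

  rules <- config$rules
  if (!is.null(config$molecules)) {
    say("stage: biophysics (deriving local rules)")
    rules <- local_rules_from_biophysics(config$molecules$A,
                                         config$molecules$B,
                                         config$molecules$dimension)
    ranges <- attr(rules, "ranges")
    tab <- data.frame(type = c("A", "B"),
                      R = as.numeric(ranges),
                      r = c(rules$r_A, rules$r_B),
                      mu_hat = c(rules$mu_hat_A, rules$mu_hat_B),
                      swapped = rules$swapped)
    p <- file.path(out_dir, "local_rules.tsv")
    write_tsv(tab, p, list(stage = "biophysics"))
    manifest$stages <- c(manifest$stages, "biophysics")
    manifest$outputs$local_rules <- p
  }
  if (is.null(rules))
    stop("pipeline needs local rules (direct or from molecular parameters)",
         call. = FALSE)

  say("stage: pair approximation equilibrium")
  eq <- productivity(rules)
  eq_tab <- data.frame(P_A = eq$P_A, P_BgA = eq$P_BgA, P_AgB = eq$P_AgB,
                       productivity_spatial = eq$productivity_spatial,
                       productivity_wm = eq$productivity_wm,
                       productivity_ratio = eq$productivity_ratio,
                       collapsed = eq$collapsed)
  p <- file.path(out_dir, "equilibrium.tsv")
  write_tsv(eq_tab, p, list(stage = "pair_approximation"))
  manifest$stages <- c(manifest$stages, "pair_approximation")
  manifest$outputs$equilibrium <- p

  if (!is.null(config$ca)) {
    say("stage: cellular automaton ensemble")
    cac <- config$ca
    seed <- as.integer(seed %||% cac$seed %||% config$pipeline$seed %||% 1L)
    n_rep <- as.integer(n_replicates %||% config$pipeline$n_replicates %||% 8L)
    cfg <- ca_config(d_A = cac$d_A, d_B = cac$d_B,
                     mu_hat_A = rules$mu_hat_A, mu_hat_B = rules$mu_hat_B,
                     height = cac$height %||% 100,
                     width = cac$width %||% 100,
                     d_R = cac$d_R %||% min(cac$d_A, cac$d_B),
                     growth_model = rules$growth_model,
                     init_freq_A = cac$init_freq_A %||% 0.5,
                     seed = seed,
                     n_events = cac$n_events %||% 100000)
    ens <- ca_ensemble(cfg, n_replicates = n_rep)
    p <- file.path(out_dir, "ca_ensemble.tsv")
    write_tsv(ens$replicates, p,
              list(stage = "cellular_automaton",
                   seeds = paste(ens$replicates$seed, collapse = ",")))
    manifest$stages <- c(manifest$stages, "cellular_automaton")
    manifest$outputs$ca_ensemble <- p
    manifest$seeds$ca <- ens$replicates$seed

    say("stage: comparison")
    get <- function(o, f) ens$summary[[f]][ens$summary$observable == o]
    cmp <- data.frame(
      observable = c("P_A", "P_BgA", "P_AgB"),
      pair_approximation = c(eq$P_A, eq$P_BgA, eq$P_AgB),
      ca_mean = c(get("P_A", "mean"), get("P_BgA", "mean"),
                  get("P_AgB", "mean")),
      ca_ci_lower = c(get("P_A", "ci_lower"), get("P_BgA", "ci_lower"),
                      get("P_AgB", "ci_lower")),
      ca_ci_upper = c(get("P_A", "ci_upper"), get("P_BgA", "ci_upper"),
                      get("P_AgB", "ci_upper")))
    p <- file.path(out_dir, "comparison.tsv")
    write_tsv(cmp, p, list(stage = "comparison"))
    manifest$stages <- c(manifest$stages, "comparison")
    manifest$outputs$comparison <- p
  }

  mp <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  manifest$outputs$manifest <- mp
  invisible(manifest)
}
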