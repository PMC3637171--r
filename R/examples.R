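# Packaged example systems: negative autoregulation with and without a
# translation delay, a mutual-repression toggle-switch colony, and the
# metabolic flux model with balanced vs unbalanced gene placement.

.example_names <- c("negautoreg", "negautoreg_delay", "toggle",
                    "flux_balanced", "flux_unbalanced")

#' Load a packaged example model
#'
#' @param name one of `"negautoreg"`, `"negautoreg_delay"`, `"toggle"`,
#'   `"flux_balanced"`, `"flux_unbalanced"`.
#' @return As [read_model()]: list with `model` and `config`.
#' @export
example_model <- function(name) {
  name <- match.arg(name, .example_names)
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "growSSA")
  if (!nzchar(path)) stop("packaged model not found: ", name)
  read_model(path)
}

#' Path of a packaged example model file
#' @inheritParams example_model
#' @return File path.
#' @export
example_model_path <- function(name) {
  name <- match.arg(name, .example_names)
  system.file("extdata", "models", paste0(name, ".json"),
              package = "growSSA")
}

#' Run a packaged example end to end
#'
#' Deterministic given `seed`. Each example returns its trajectories plus
#' a summary holding the example's acceptance properties:
#' * `negautoreg` — single lineage over two 200-min generations; summary:
#'   time-averaged protein count, the ODE steady-state count at birth
#'   volume, their ratio (growth pushes the stochastic mean above the
#'   fixed-volume deterministic value), and the oscillation score
#'   (expected above -0.3: no oscillation without delay).
#' * `negautoreg_delay` — the same circuit with a 1000 s translation
#'   delay; summary: engine and delay-ODE oscillation scores (both
#'   expected below -0.3).
#' * `toggle` — a colony of mutually repressing genes; summary: Pearson
#'   correlation of cycle-averaged protein A vs protein B across the last
#'   complete generation (expected negative: epigenetically inherited
#'   anticorrelated states).
#' * `flux_balanced` / `flux_unbalanced` — single lineage of the
#'   metabolic model; summary: time-averaged M2 count and its standard
#'   deviation after a two-generation burn-in, plus each gene's copies at
#'   birth and doubling age from the replication schedule.
#'
#' @param name example name (see [example_model()]).
#' @param seed integer seed.
#' @param t_end optional horizon override in seconds (used by the test
#'   suite to run scaled-down versions).
#' @return A list: `name`, `seed`, `summary` (list), and `trajectory`
#'   and/or `tree`, `config`.
#' @export
run_example <- function(name, seed = 1L, t_end = NULL) {
  name <- match.arg(name, .example_names)
  md <- example_model(name)
  config <- md$config
  config$seed <- as.integer(seed)
  if (!is.null(t_end)) config$t_end <- t_end
  model <- md$model
  out <- list(name = name, seed = as.integer(seed), config = config)

  if (name %in% c("negautoreg", "negautoreg_delay")) {
    lin <- simulate_lineage(model, config)
    tr <- lin$trajectory
    burn <- min(2000, 0.1 * config$t_end)
    win <- tr$time_s >= burn
    mean_protein <- mean(tr$protein[win])
    ss <- autoreg_steady_state()
    ss_count <- ss[["protein"]] * omega_factor(config$V_birth)
    span <- max(tr$time_s) - burn
    osc <- oscillation_score(tr$time_s, tr$protein / tr$volume_L,
                             burn = burn, window = min(5000, span / 3),
                             max_lag = min(5000, span / 3))
    out$trajectory <- tr
    out$summary <- list(
      mean_protein_count = mean_protein,
      ode_steady_state_count = ss_count,
      ratio_vs_ode = mean_protein / ss_count,
      oscillation_score = as.numeric(osc),
      oscillating = as.numeric(osc) < -0.3,
      generations = lin$generations)
    if (name == "negautoreg_delay") {
      dde <- integrate_delayed_ode(delay = 1000, t_end = config$t_end)
      osc_dde <- oscillation_score(dde$time_s, dde$protein)
      out$summary$dde_oscillation_score <- as.numeric(osc_dde)
      out$summary$dde_oscillating <- as.numeric(osc_dde) < -0.3
    }
  } else if (name == "toggle") {
    tree <- simulate_colony(model, config)
    nd <- tree$nodes
    complete <- nd[!is.na(nd$division_s), ]
    last_gen <- max(complete$generation)
    ids <- complete$cell_id[complete$generation == last_gen]
    r <- lineage_correlation(tree, "protein_A", "protein_B", cells = ids)
    out$tree <- tree
    out$summary <- list(
      n_cells = nrow(nd), analysed_generation = last_gen,
      n_analysed = length(ids), lineage_correlation = r,
      anticorrelated = is.finite(r) && r < 0)
  } else {
    lin <- simulate_lineage(model, config)
    tr <- lin$trajectory
    burn <- min(2 * config$T * 60, 0.5 * config$t_end)
    win <- tr$time_s >= burn
    per <- config$periods
    gpos <- vapply(model$genes, `[[`, 0, "position")
    out$trajectory <- tr
    out$summary <- list(
      mean_M2_count = mean(tr$M2[win]),
      sd_M2_count = stats::sd(tr$M2[win]),
      mean_M2_conc_uM = mean(tr$M2[win] / omega_factor(tr$volume_L[win])),
      copies_at_birth = vapply(gpos, copies_at_birth, 0L, periods = per),
      doubling_age_min = vapply(gpos, replication_age, 0, periods = per),
      generations = lin$generations)
  }
  out
}
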