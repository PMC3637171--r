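# Model file reader/writer (JSON), output writers, CLI entry point.

.model_keys <- list(
  top = c("species", "reactions", "genes", "config"),
  species = c("name", "initial_count", "partition_at_division"),
  reaction = c("name", "reactants", "products", "rate", "rate_units",
               "volume_class", "delay", "rate_law", "enzyme", "substrate",
               "Km", "noise"),
  gene = c("name", "position", "rate", "rate_units", "mrna", "sites",
           "delay", "initial_copies", "cooperativity", "noise"),
  site = c("tf", "kon", "koff", "factor"),
  config = c("T", "C", "D", "V_birth", "t_end", "grid_dt", "seed",
             "max_cells", "noise"),
  noise = c("tau_c", "sigma", "applied_to", "eta0"))

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("%s: unknown key '%s'", where, bad[1L]), call. = FALSE)
  x
}

#' Read a model definition file
#'
#' The file is JSON with top-level keys `species`, `reactions`, `genes`
#' and optionally `config`; see the packaged examples under
#' `system.file("extdata", "models", package = "growSSA")` for the exact
#' schema. Parsing failures and unknown keys are reported with the
#' offending field named; the model is validated through [build_model()].
#'
#' @param path file path.
#' @return A list with `model` (`grow_model`) and `config`
#'   ([run_config()] or `NULL` when the file carries none).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!is.list(raw) || is.null(names(raw)))
    stop("parse error: model file must be a JSON object")
  check_keys(raw, .model_keys$top, "model file")
  num_or_null <- function(x) if (is.null(x)) NULL else as.numeric(x)
  species <- lapply(raw$species, function(s) {
    check_keys(s, .model_keys$species, sprintf("species '%s'", s$name))
    species_def(s$name,
                initial_count = if (is.null(s$initial_count)) 0L
                                else s$initial_count,
                partition_at_division =
                  if (is.null(s$partition_at_division)) TRUE
                  else s$partition_at_division)
  })
  reactions <- lapply(raw$reactions, function(r) {
    check_keys(r, .model_keys$reaction, sprintf("reaction '%s'", r$name))
    reaction_def(r$name,
                 reactants = unlist(r$reactants), products = unlist(r$products),
                 rate = r$rate, rate_units = r$rate_units,
                 volume_class = r$volume_class,
                 delay = if (is.null(r$delay)) 0 else r$delay,
                 rate_law = if (is.null(r$rate_law)) "mass_action"
                            else r$rate_law,
                 enzyme = r$enzyme, substrate = r$substrate,
                 Km = num_or_null(r$Km), noise = isTRUE(r$noise))
  })
  genes <- lapply(raw$genes, function(g) {
    check_keys(g, .model_keys$gene, sprintf("gene '%s'", g$name))
    sites <- lapply(g$sites, function(s) {
      check_keys(s, .model_keys$site,
                 sprintf("gene '%s' binding site", g$name))
      binding_site(s$tf, s$kon, s$koff, s$factor)
    })
    gene_def(g$name, g$position, g$rate, g$mrna, sites = sites,
             delay = if (is.null(g$delay)) 0 else g$delay,
             initial_copies = g$initial_copies,
             cooperativity = num_or_null(unlist(g$cooperativity)),
             noise = isTRUE(g$noise))
  })
  model <- build_model(list(species = species, reactions = reactions,
                            genes = genes))
  config <- NULL
  if (!is.null(raw$config)) {
    cf <- check_keys(raw$config, .model_keys$config, "config")
    noise <- NULL
    if (!is.null(cf$noise)) {
      nz <- check_keys(cf$noise, .model_keys$noise, "config$noise")
      noise <- ou_params(nz$tau_c,
                         sigma = if (is.null(nz$sigma)) 0.1 else nz$sigma,
                         applied_to = as.character(unlist(nz$applied_to)),
                         eta0 = if (is.null(nz$eta0)) 0 else nz$eta0)
    }
    config <- run_config(T = cf$T,
                         C = if (is.null(cf$C)) 40 else cf$C,
                         D = if (is.null(cf$D)) 20 else cf$D,
                         V_birth = if (is.null(cf$V_birth)) 1.1e-15
                                   else cf$V_birth,
                         t_end = cf$t_end,
                         grid_dt = if (is.null(cf$grid_dt)) 1 else cf$grid_dt,
                         seed = if (is.null(cf$seed)) 1L else cf$seed,
                         max_cells = if (is.null(cf$max_cells)) 1024L
                                     else cf$max_cells,
                         noise = noise)
  }
  list(model = model, config = config)
}

#' Write a model (and optional config) to a JSON model file
#'
#' Inverse of [read_model()]: `build_model(read_model(write_model(m))$...)`
#' round-trips to an identical model.
#'
#' @param model a `grow_model`.
#' @param path output path.
#' @param config optional [run_config()].
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, config = NULL) {
  stopifnot(inherits(model, "grow_model"))
  strip <- function(x) x[!vapply(x, is.null, TRUE)]
  out <- list(
    species = lapply(model$species, function(s)
      strip(list(name = s$name, initial_count = s$initial_count,
                 partition_at_division = s$partition_at_division))),
    reactions = lapply(model$reactions, function(r)
      strip(list(name = r$name,
                 reactants = if (length(r$reactants)) as.list(r$reactants),
                 products = if (length(r$products)) as.list(r$products),
                 rate = r$rate, rate_units = r$rate_units,
                 volume_class = if (r$rate_law == "mass_action")
                   r$volume_class,
                 delay = if (r$delay > 0) r$delay,
                 rate_law = if (r$rate_law != "mass_action") r$rate_law,
                 enzyme = r$enzyme, substrate = r$substrate, Km = r$Km,
                 noise = if (r$noise) TRUE))),
    genes = lapply(model$genes, function(g)
      strip(list(name = g$name, position = g$position, rate = g$rate,
                 mrna = g$mrna,
                 sites = lapply(g$sites, function(s)
                   list(tf = s$tf, kon = s$kon, koff = s$koff,
                        factor = s$factor)),
                 delay = if (g$delay > 0) g$delay,
                 initial_copies = g$initial_copies,
                 cooperativity = g$cooperativity,
                 noise = if (g$noise) TRUE))))
  if (!is.null(config)) {
    nz <- config$noise
    out$config <- strip(list(
      T = config$T, C = config$C, D = config$D, V_birth = config$V_birth,
      t_end = config$t_end, grid_dt = config$grid_dt, seed = config$seed,
      max_cells = config$max_cells,
      noise = if (!is.null(nz))
        list(tau_c = nz$tau_c, sigma = nz$sigma,
             applied_to = as.list(nz$applied_to), eta0 = nz$eta0)))
  }
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Write simulation outputs to a directory
#'
#' Produces per-cell trajectory TSVs (`cell_<id>.tsv`, columns `time_s`,
#' `volume_L`, one per species and `copies_<gene>`), a Newick lineage
#' file (`lineage.nwk`) for colony runs, a JSON summary
#' (`summary.json`: seed, config echo, metrics) and a plain `run.log`.
#' Outputs contain no timestamps, so a re-run with the same seed is
#' byte-identical.
#'
#' @param result a `lineage_tree`, or a list with elements among `tree`,
#'   `trajectory`, `summary`, `config`, `seed`.
#' @param outdir directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  files <- character(0)
  tsv <- function(df, fn) {
    p <- file.path(outdir, fn)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  tree <- NULL
  if (inherits(result, "lineage_tree")) tree <- result
  else if (!is.null(result$tree)) tree <- result$tree
  if (!is.null(tree)) {
    for (nm in names(tree$trajectories))
      tsv(tree$trajectories[[nm]], paste0(nm, ".tsv"))
    p <- file.path(outdir, "lineage.nwk")
    writeLines(lineage_newick(tree, annotate = TRUE), p)
    files <- c(files, p)
    tsv(tree$nodes, "cells.tsv")
  }
  if (!inherits(result, "lineage_tree") && !is.null(result$trajectory))
    tsv(result$trajectory, "trajectory.tsv")
  summ <- list(seed = if (!is.null(tree)) tree$seed else result$seed,
               summary = if (!inherits(result, "lineage_tree"))
                 result$summary)
  if (!inherits(result, "lineage_tree") && !is.null(result$config)) {
    cf <- result$config
    summ$config <- list(T = cf$T, C = cf$C, D = cf$D,
                        V_birth = cf$V_birth, t_end = cf$t_end,
                        grid_dt = cf$grid_dt, seed = cf$seed,
                        max_cells = cf$max_cells)
  }
  p <- file.path(outdir, "summary.json")
  writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), p)
  files <- c(files, p)
  p <- file.path(outdir, "run.log")
  writeLines(c("growSSA run",
               sprintf("files: %d", length(files)),
               sprintf("cells: %s",
                       if (!is.null(tree)) nrow(tree$nodes) else 1L)), p)
  files <- c(files, p)
  invisible(files)
}

# --- minimal CLI ------------------------------------------------------

cli_opts <- function(args) {
  opts <- list(pos = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", sub("^--", "", a))
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      opts$pos <- c(opts$pos, a)
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `validate <model>`, `simulate <model> [--t-end S] [--seed N]
#' [--max-cells N] [--out DIR]`, `classic-ssa <model> [--t-end S] [--seed N]
#' [--out DIR]`, `dosage --p P --T T [--C C] [--D D]`,
#' `ode [--t-end S]` / `dde [--delay S] [--t-end S]` (autoregulation
#' reference solvers), `run-example <name> [--seed N] [--out DIR]`.
#' An executable wrapper is installed at
#' `system.file("cli", "growssa", package = "growSSA")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Exit status 0, invisibly (errors raise conditions).
#' @export
growssa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: growssa <validate|simulate|classic-ssa|dosage|ode|dde|run-example> ...\n")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  o <- cli_opts(args[-1L])
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  switch(cmd,
    validate = {
      md <- read_model(o$pos[1L])
      cat(sprintf("OK: %d species, %d reactions, %d genes\n",
                  length(md$model$species), length(md$model$reactions),
                  length(md$model$genes)))
    },
    dosage = {
      per <- cycle_periods(num(o$T, 50), num(o$C, 40), num(o$D, 20))
      p <- num(o$p, 0)
      cat(sprintf("replication age: %g min\ncopies at birth: %d\nmean dosage: %g\n",
                  replication_age(p, per), copies_at_birth(p, per),
                  population_mean_dosage(p, per)))
    },
    simulate = {
      md <- read_model(o$pos[1L])
      cf <- md$config
      if (is.null(cf)) stop("model file has no config block")
      if (!is.null(o$t_end)) cf$t_end <- as.numeric(o$t_end)
      if (!is.null(o$seed)) cf$seed <- as.integer(o$seed)
      if (!is.null(o$max_cells)) cf$max_cells <- as.integer(o$max_cells)
      tree <- simulate_colony(md$model, cf)
      cat(sprintf("simulated %d cells to t = %g s (seed %d)\n",
                  nrow(tree$nodes), cf$t_end, cf$seed))
      if (!is.null(o$out)) write_outputs(tree, o$out)
    },
    `classic-ssa` = {
      md <- read_model(o$pos[1L])
      cf <- md$config
      flat <- flatten_gene_model(md$model,
                                 periods = if (!is.null(cf)) cf$periods)
      set.seed(if (!is.null(o$seed)) as.integer(o$seed)
               else if (!is.null(cf)) cf$seed else 1L)
      res <- classic_ssa(flat, t_end = num(o$t_end,
                                           if (!is.null(cf)) cf$t_end else 1000),
                         V = if (!is.null(cf)) cf$V_birth else 1.1e-15)
      cat(sprintf("classic SSA: %g events\n", res$n_events))
      if (!is.null(o$out)) {
        dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(res$trajectory,
                           file.path(o$out, "trajectory.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    },
    ode = {
      ss <- autoreg_steady_state()
      tr <- integrate_autoreg_ode(t_end = num(o$t_end, 24000))
      cat(sprintf("autoregulation ODE: steady-state protein %.6g uM (%.4g molecules at birth volume)\n",
                  ss[["protein"]],
                  ss[["protein"]] * omega_factor(1.1e-15)))
      if (!is.null(o$out)) {
        dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(tr, file.path(o$out, "ode.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    },
    dde = {
      tr <- integrate_delayed_ode(delay = num(o$delay, 1000),
                                  t_end = num(o$t_end, 24000))
      sc <- oscillation_score(tr$time_s, tr$protein)
      cat(sprintf("delay ODE: oscillation score %.3f (%s)\n", sc,
                  if (sc < -0.3) "oscillating" else "not oscillating"))
      if (!is.null(o$out)) {
        dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(tr, file.path(o$out, "dde.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    },
    `run-example` = {
      res <- run_example(o$pos[1L],
                         seed = if (!is.null(o$seed)) as.integer(o$seed)
                                else 1L)
      str_sum <- jsonlite::toJSON(res$summary, auto_unbox = TRUE,
                                  pretty = TRUE, digits = NA)
      cat(str_sum, "\n")
      if (!is.null(o$out)) write_outputs(res, o$out)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(0L)
}
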