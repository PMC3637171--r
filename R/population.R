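# Division, binomial partitioning, promoter-state inheritance and
# lineage-tree bookkeeping.

#' Binomial partitioning of free molecules at division
#'
#' Each free molecule goes to daughter 1 with probability 1/2, so per
#' species `d1 ~ Binomial(n, 1/2)` and `d2 = n - d1`: if one daughter
#' gets more, the other gets less, exactly. Species flagged
#' `partition_at_division = FALSE` (chromosome-associated entities) are
#' not split: both daughters inherit the full count alongside their
#' chromosome complement.
#'
#' @param counts named nonnegative integer vector.
#' @param partition logical vector (recycled) marking which species are
#'   free molecules; default all `TRUE`.
#' @return `list(d1 = , d2 = )` of named integer vectors with
#'   `d1 + d2 == counts` for every partitioned species.
#' @export
partition_binomial <- function(counts, partition = TRUE) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  counts <- as.integer(counts) |> stats::setNames(names(counts))
  partition <- rep_len(partition, length(counts))
  d1 <- counts
  d1[partition] <- vapply(counts[partition],
                          function(n) stats::rbinom(1L, n, 0.5), 0L)
  d2 <- counts
  d2[partition] <- counts[partition] - d1[partition]
  list(d1 = d1, d2 = d2)
}

#' Divide a cell into two daughters
#'
#' Free molecules are partitioned binomially; gene instances are split by
#' chromosome tag (the two sister copies created at the last replication
#' separate), each daughter receiving an equal complement of gene copies
#' with their promoter occupancy states intact — bound TFs travel with
#' their instance. Pending delayed releases are assigned to a daughter by
#' an independent fair coin (delayed products in this framework are free
#' molecules once released; see the methods vignette). Both daughters are
#' born with volume `V_birth` at the mother's division time.
#'
#' @param cell a `cell_state` at its division age (`t = t_birth + T`).
#' @param model the `grow_model` (for species partition flags).
#' @return `list(d1 = , d2 = )` of newborn `cell_state`s.
#' @export
divide <- function(cell, model) {
  stopifnot(inherits(cell, "cell_state"))
  if (abs(cell$t - (cell$t_birth + cell$T_s)) > 1e-6 * cell$T_s)
    stop("divide(): cell is not at its division age")
  flags <- if (inherits(model, "grow_model"))
    vapply(model$species, `[[`, TRUE, "partition_at_division")
  else TRUE
  parts <- partition_binomial(cell$counts, flags)
  mk <- function(counts) {
    d <- cell
    d$t <- d$t_birth <- cell$t
    d$counts <- counts
    d$queue <- empty_queue()
    d
  }
  d1 <- mk(parts$d1); d2 <- mk(parts$d2)
  for (k in seq_along(cell$genes)) {
    gs <- cell$genes[[k]]
    i1 <- which(gs$tag == 1L); i2 <- which(gs$tag == 2L)
    if (length(i1) != length(i2))
      stop(sprintf(
        "internal scheduling error: gene %d has an unsplittable complement (%d vs %d copies)",
        k, length(i1), length(i2)))
    d1$genes[[k]] <- list(bound = gs$bound[i1, , drop = FALSE],
                          tag = rep_len(c(1L, 2L), length(i1)))
    d2$genes[[k]] <- list(bound = gs$bound[i2, , drop = FALSE],
                          tag = rep_len(c(1L, 2L), length(i2)))
  }
  if (nrow(cell$queue)) {
    coin <- stats::runif(nrow(cell$queue)) < 0.5
    d1$queue <- cell$queue[coin, , drop = FALSE]
    d2$queue <- cell$queue[!coin, , drop = FALSE]
    rownames(d1$queue) <- rownames(d2$queue) <- NULL
  }
  list(d1 = d1, d2 = d2)
}

cell_seed <- function(seed, cell_id) {
  (as.double(seed %% 100003L) * 20011 + as.double(cell_id) * 7919) %%
    2147483629 + 1
}

#' Simulate a colony as a binary lineage tree
#'
#' Breadth-first simulation of every cell: the root is born at `t = 0`,
#' each cell runs one generation with [run_cell()] and, if its division
#' time falls within the horizon, is split with [divide()] into daughters
#' `2 i` and `2 i + 1` (heap numbering). Per-cell RNG substreams are
#' derived deterministically from `(seed, cell_id)`, so colonies are fully
#' reproducible. Exceeding `max_cells` truncates the tree (recorded in
#' `$truncated`).
#'
#' @param model a `grow_model`.
#' @param config a [run_config()]; `t_end`, `seed` and `max_cells` bound
#'   the work.
#' @param init optional `cell_state` for the root.
#' @return A `lineage_tree`: `nodes` (data.frame `cell_id`, `parent_id`,
#'   `generation`, `birth_s`, `division_s` — `NA` for cells that did not
#'   divide — and `n_events`), `trajectories` (named list of per-cell
#'   data.frames), `t_end`, `seed`, `truncated`.
#' @export
simulate_colony <- function(model, config, init = NULL) {
  stopifnot(inherits(config, "run_config"))
  root <- if (is.null(init)) new_cell_state(model, config) else init
  todo <- list(list(id = 1L, parent = 0L, gen = 0L, state = root))
  nodes <- list(); trajs <- list(); truncated <- FALSE
  n_alive <- 1L
  while (length(todo)) {
    it <- todo[[1L]]; todo <- todo[-1L]
    set.seed(cell_seed(config$seed, it$id))
    res <- run_cell(it$state, model, config)
    kids <- NULL
    if (res$divided) {
      if (n_alive + 2L <= config$max_cells) {
        kids <- divide(res$state, model)
        n_alive <- n_alive + 2L
      } else {
        if (!truncated)
          warning("max_cells reached: lineage tree truncated",
                  call. = FALSE)
        truncated <- TRUE
      }
    }
    nodes[[length(nodes) + 1L]] <- data.frame(
      cell_id = it$id, parent_id = it$parent, generation = it$gen,
      birth_s = it$state$t_birth,
      division_s = if (!is.null(kids)) res$state$t else NA_real_,
      n_events = res$n_events)
    trajs[[paste0("cell_", it$id)]] <- res$trajectory
    if (!is.null(kids)) {
      todo <- c(todo, list(
        list(id = 2L * it$id, parent = it$id, gen = it$gen + 1L,
             state = kids$d1),
        list(id = 2L * it$id + 1L, parent = it$id, gen = it$gen + 1L,
             state = kids$d2)))
    }
  }
  nodes <- do.call(rbind, nodes)
  nodes <- nodes[order(nodes$cell_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, trajectories = trajs,
                 t_end = config$t_end, seed = config$seed,
                 truncated = truncated),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: %d cells, %d generations, t_end = %g s%s\n",
              nrow(x$nodes), max(x$nodes$generation) + 1L, x$t_end,
              if (x$truncated) " (truncated at max_cells)" else ""))
  invisible(x)
}

#' Long-format trajectory table of a colony
#'
#' One row per (cell, time, species) — the heatmap-ready layout used for
#' lineage expression plots.
#'
#' @param x a `lineage_tree`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return A data.frame with columns `cell_id`, `time_s`, `species`,
#'   `value`.
#' @export
as.data.frame.lineage_tree <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  out <- lapply(names(x$trajectories), function(nm) {
    tr <- x$trajectories[[nm]]
    id <- as.integer(sub("cell_", "", nm))
    sp <- setdiff(colnames(tr), c("time_s", "volume_L"))
    do.call(rbind, lapply(sp, function(s)
      data.frame(cell_id = id, time_s = tr$time_s, species = s,
                 value = tr[[s]])))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# time-weighted mean of a trajectory column over the cell's lifetime
traj_time_mean <- function(tr, column) {
  n <- nrow(tr)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(as.numeric(tr[[column]][1L]))
  dt <- diff(tr$time_s)
  # step-function (sample-and-hold) time average on the output grid
  sum(tr[[column]][-n] * dt) / sum(dt)
}

#' Cross-cell correlation of cycle-averaged expression
#'
#' For every selected cell, computes the time-weighted mean of each
#' species over the cell's lifetime, then the Pearson correlation across
#' cells. Mutual repressors in a bistable toggle yield a negative
#' correlation; independent constitutive genes yield one near zero.
#'
#' @param tree a `lineage_tree`.
#' @param speciesA,speciesB species (column) names.
#' @param cells `"all"`, `"complete"` (only cells that divided within the
#'   horizon), `"leaves"`, or an integer vector of cell ids.
#' @return Pearson `r` in `[-1, 1]`; `NA` (with a message) if either
#'   cycle-average series is constant. Needs at least 3 usable cells.
#' @export
lineage_correlation <- function(tree, speciesA, speciesB, cells = "all") {
  stopifnot(inherits(tree, "lineage_tree"))
  ids <- if (is.numeric(cells)) as.integer(cells)
  else switch(match.arg(cells, c("all", "complete", "leaves")),
    all = tree$nodes$cell_id,
    complete = tree$nodes$cell_id[!is.na(tree$nodes$division_s)],
    leaves = setdiff(tree$nodes$cell_id,
                     unique(tree$nodes$parent_id)))
  a <- b <- rep(NA_real_, length(ids))
  for (q in seq_along(ids)) {
    tr <- tree$trajectories[[paste0("cell_", ids[q])]]
    if (is.null(tr) || nrow(tr) < 2L) next
    a[q] <- traj_time_mean(tr, speciesA)
    b[q] <- traj_time_mean(tr, speciesB)
  }
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L)
    stop("lineage_correlation needs at least 3 cells with trajectories")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    message("constant cycle-average series: correlation undefined")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok])
}

#' Newick export of the lineage tree
#'
#' Branch lengths are cell lifetimes in seconds (leaves truncated at
#' `t_end`); tip and node labels are `c<cell_id>`. With
#' `annotate = TRUE`, New Hampshire eXtended-style comments
#' `[&cell_id=..,birth=..,division=..]` are attached (plain output parses
#' with standard Newick readers, e.g. `ape::read.tree`).
#'
#' @param tree a `lineage_tree`.
#' @param annotate logical.
#' @return A single Newick string (terminated by `;`).
#' @export
lineage_newick <- function(tree, annotate = FALSE) {
  nd <- tree$nodes
  rec <- function(id) {
    row <- nd[nd$cell_id == id, ]
    kids <- nd$cell_id[nd$parent_id == id]
    life <- (if (is.na(row$division_s)) tree$t_end else row$division_s) -
      row$birth_s
    ann <- if (annotate)
      sprintf("[&cell_id=%d,birth=%g,division=%s]", id, row$birth_s,
              if (is.na(row$division_s)) "NA" else
                sprintf("%g", row$division_s))
    else ""
    if (length(kids) == 0L)
      sprintf("c%d%s:%g", id, ann, life)
    else
      sprintf("(%s,%s)c%d%s:%g", rec(kids[1L]), rec(kids[2L]), id, ann,
              life)
  }
  paste0(rec(nd$cell_id[nd$parent_id == 0L]), ";")
}

#' Simulate a single cell line over several generations
#'
#' Runs one cell to division, keeps daughter 1, and repeats — the
#' "follow one lineage" view used for long time series (oscillation
#' scoring, metabolite statistics). RNG substreams per generation follow
#' the same `(seed, cell_id)` rule as [simulate_colony()] along the
#' leftmost path, so the path reproduces the corresponding colony cells.
#'
#' @param model a `grow_model`.
#' @param config a [run_config()]; the number of generations is
#'   `ceiling(t_end / (60 T))`.
#' @return A list: `trajectory` (concatenated data.frame with a `cell_id`
#'   column), `generations`, `final_state`.
#' @export
simulate_lineage <- function(model, config) {
  state <- new_cell_state(model, config)
  id <- 1L
  out <- list()
  repeat {
    set.seed(cell_seed(config$seed, id))
    res <- run_cell(state, model, config)
    tr <- res$trajectory
    tr$cell_id <- id
    out[[length(out) + 1L]] <- tr
    if (!res$divided) break
    state <- divide(res$state, model)$d1
    id <- 2L * id
  }
  traj <- do.call(rbind, out)
  # drop duplicated boundary instants (division time appears in both cells)
  traj <- traj[!duplicated(traj$time_s), , drop = FALSE]
  rownames(traj) <- NULL
  list(trajectory = traj, generations = length(out), final_state = state)
}
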