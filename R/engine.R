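# The modified SSA: split propensities by volume-scaling class, exact
# firing-time sampling under exponential volume growth, and the event loop
# with scheduled replication / delayed-release events.

#' Cumulative hazard of the growth-modulated total propensity
#'
#' Between reaction events the molecule counts are constant and the total
#' propensity depends on time only through the volume
#' `V(t + s) = V(t) e^(mu s)`:
#' `a(s) = A + b e^(-mu s) + g e^(mu s)`, where `A` collects
#' volume-independent channels, `b` the inverse-volume (bimolecular)
#' channels evaluated at `s = 0`, and `g` the proportional-volume influxes
#' at `s = 0`. The cumulative hazard is
#' `Lambda(tau) = A tau + (b/mu)(1 - e^(-mu tau)) + (g/mu)(e^(mu tau) - 1)`
#' and `P(no reaction in tau) = e^(-Lambda(tau))`.
#'
#' @param A,b,g nonnegative propensity totals (1/s) by volume class.
#' @param mu volume growth rate `ln(2)/T` (1/s); `mu <= 0` gives the
#'   constant-volume limit `(A+b+g) tau`.
#' @param tau waiting interval in seconds.
#' @return `Lambda(tau)`, dimensionless.
#' @export
survival_integral <- function(A, b, g = 0, mu, tau) {
  cpp_survival_integral(A, b, g, mu, tau)
}

#' Sample the next firing time under exponential volume growth
#'
#' Inverts `Lambda(tau) = -log(r)` for a uniform draw `r`. Branches:
#' `b = g = 0` reduces to the classic SSA (`tau = L/A`); `A = g = 0` has a
#' bounded total hazard `b/mu`, so the sampler returns `Inf`
#' (`NO_FIRING`) when `mu L / b >= 1`; `A, b > 0, g = 0` uses the
#' closed form through the principal branch of the Lambert W function,
#' `tau = (L - b/mu)/A + W0((b/A) e^(-mu (L - b/mu)/A)) / mu`,
#' followed by a Newton polish on the hazard residual; any case with
#' `g > 0` falls back to safeguarded Newton/bisection. The result
#' satisfies `|Lambda(tau) + log(r)| <= 1e-10 (1 + |log r|)` — the
#' precision safeguard that keeps densely scheduled delayed releases from
#' starving ordinary channels.
#'
#' @inheritParams survival_integral
#' @param r uniform(0,1) random number.
#' @return Waiting time in seconds, or `Inf` if no reaction ever fires.
#' @examples
#' sample_firing_time(A = 1, b = 0, mu = 0.01, r = exp(-1))  # 1, classic
#' sample_firing_time(A = 0, b = 1, mu = 1, r = exp(-2))     # Inf
#' @export
sample_firing_time <- function(A, b, g = 0, mu, r) {
  cpp_sample_firing_time(A, b, g, mu, r)
}

#' Principal branch of the Lambert W function
#'
#' Solves `w e^w = x` for `x >= -1/e`; used by [sample_firing_time()].
#' @param x numeric scalar.
#' @return `W0(x)`.
#' @export
lambert_w0 <- function(x) cpp_lambert_w0(x)

#' Simulation run configuration
#'
#' @param T,C,D cell-cycle periods in minutes (see [cycle_periods()]).
#' @param V_birth cell volume at birth, litres. Default `1.1e-15` L
#'   (typical *E. coli*), for which 1 uM is about 662.4 molecules.
#' @param t_end simulation horizon in seconds.
#' @param grid_dt trajectory output grid step, seconds.
#' @param seed integer RNG seed; per-cell substreams are derived
#'   deterministically from `(seed, cell_id)`.
#' @param max_cells colony-size cap for [simulate_colony()].
#' @param noise optional [ou_params()] extrinsic-noise block.
#' @return A `run_config` object.
#' @export
run_config <- function(T, C = 40, D = 20, V_birth = 1.1e-15, t_end,
                       grid_dt = 1, seed = 1L, max_cells = 1024L,
                       noise = NULL) {
  periods <- cycle_periods(T, C, D)
  stopifnot(is.numeric(V_birth), V_birth > 0,
            is.numeric(t_end), t_end > 0,
            is.numeric(grid_dt), grid_dt > 0,
            is.numeric(seed), length(seed) == 1L,
            is.numeric(max_cells), max_cells >= 1)
  if (!is.null(noise) && !inherits(noise, "ou_params"))
    stop("`noise` must be an ou_params() object")
  structure(list(periods = periods, T = T, C = C, D = D,
                 V_birth = V_birth, t_end = t_end, grid_dt = grid_dt,
                 seed = as.integer(seed), max_cells = as.integer(max_cells),
                 noise = noise),
            class = "run_config")
}

#' Create the state of a newborn cell
#'
#' Counts come from the species' `initial_count`; each gene is
#' instantiated with its Cooper-Helmstetter copy number at birth (or the
#' gene's `initial_copies` override), every instance starting with an
#' unoccupied promoter.
#'
#' @param model a `grow_model`.
#' @param config a [run_config()].
#' @param t_birth birth time in seconds (absolute).
#' @return A `cell_state` object: fields `t`, `t_birth`, `T_s`, `V_birth`,
#'   `counts` (named integer vector), `genes` (per gene: `bound` 0/1
#'   matrix instances x sites, `tag` chromosome tags), `queue`
#'   (pending scheduled releases), `eta` (extrinsic-noise log-deviation).
#' @export
new_cell_state <- function(model, config, t_birth = 0) {
  stopifnot(inherits(model, "grow_model"), inherits(config, "run_config"))
  counts <- vapply(model$species, `[[`, 0L, "initial_count")
  names(counts) <- species_names(model)
  genes <- lapply(model$genes, function(g) {
    n <- if (!is.null(g$initial_copies)) g$initial_copies
         else copies_at_birth(g$position, config$periods)
    list(bound = matrix(0L, nrow = n, ncol = length(g$sites)),
         tag = rep_len(c(1L, 2L), n))
  })
  names(genes) <- vapply(model$genes, `[[`, "", "name")
  structure(list(t = t_birth, t_birth = t_birth, T_s = config$T * 60,
                 V_birth = config$V_birth, counts = counts, genes = genes,
                 queue = empty_queue(), eta = 0),
            class = "cell_state")
}

empty_queue <- function() {
  data.frame(time = numeric(0), kind = integer(0), idx = integer(0))
}

#' Cell volume at a given time
#'
#' `V(t) = V_birth * 2^((t - t_birth)/T)`, so the growth rate is
#' `mu = ln(2)/T` and the volume doubles over one generation.
#'
#' @param state a `cell_state`.
#' @param t absolute time in seconds (defaults to the state's clock).
#' @return Volume in litres.
#' @export
cell_volume <- function(state, t = state$t) {
  # exp(mu * dt) with mu = ln2/T: written exactly as in the C++ engine so
  # the two paths agree to the last bit
  state$V_birth * exp(log(2) / state$T_s * (t - state$t_birth))
}

# channel enumeration shared by the R stepper and (structurally) the C++
# engine: reactions in declaration order, then per gene / instance:
# transcription, then each site's bind-or-unbind channel.
enumerate_channels <- function(state, cm, V, noise_mult = exp(state$eta)) {
  # vector accumulators (one data.frame built at the end: this sits on the
  # hot path of the pure-R reference stepper)
  kind <- character(0); rxn <- integer(0); gene <- integer(0)
  instance <- integer(0); site <- integer(0); class <- character(0)
  value <- numeric(0)
  X <- unname(state$counts)
  if (cm$nr > 0) {
    p <- numeric(cm$nr)
    for (j in seq_len(cm$nr)) {
      vc <- cm$vclass[j]
      p[j] <- if (vc == 0L) {
        if (cm$ord[j] == 0L) cm$kappa[j] else cm$kappa[j] * X[cm$ri1[j] + 1L]
      } else if (vc == 1L) {
        if (cm$ri1[j] == cm$ri2[j]) {
          n <- X[cm$ri1[j] + 1L]
          cm$kappa[j] * n * (n - 1) / V
        } else cm$kappa[j] * X[cm$ri1[j] + 1L] * X[cm$ri2[j] + 1L] / V
      } else if (vc == 2L) {
        cm$kappa[j] * V
      } else {
        S <- X[cm$mm_s[j] + 1L]
        if (S > 0) cm$kappa[j] * X[cm$mm_e[j] + 1L] * S /
          (cm$mm_KmNA[j] * V + S) else 0
      }
      if (cm$noise[j]) p[j] <- p[j] * noise_mult
    }
    kind <- rep("reaction", cm$nr); rxn <- seq_len(cm$nr)
    gene <- instance <- site <- rep(NA_integer_, cm$nr)
    class <- c("A", "b", "g", "A")[cm$vclass + 1L]
    value <- pmax(p, 0)
  }
  for (k in seq_len(cm$ng)) {
    st <- cm$g_sites[[k]]
    gs <- state$genes[[k]]
    ns <- length(st$tf)
    ak <- cm$g_a[k] * if (cm$g_noise[k]) noise_mult else 1
    for (i in seq_len(nrow(gs$bound))) {
      bnd <- if (ns) gs$bound[i, ] else integer(0)
      nb <- sum(bnd)
      fac <- if (nb) prod(st$factor[bnd == 1L]) else 1
      kind <- c(kind, "transcription"); rxn <- c(rxn, NA_integer_)
      gene <- c(gene, k); instance <- c(instance, i)
      site <- c(site, NA_integer_); class <- c(class, "A")
      value <- c(value, ak * fac)
      for (s in seq_len(ns)) {
        if (bnd[s]) {
          kind <- c(kind, "unbind"); class <- c(class, "A")
          value <- c(value, st$koff[s])
        } else {
          coop <- if (nb + 1L <= length(st$coop)) st$coop[nb + 1L] else 1
          kind <- c(kind, "bind"); class <- c(class, "b")
          value <- c(value, st$kon[s] * coop * X[st$tf[s] + 1L] / V)
        }
        rxn <- c(rxn, NA_integer_); gene <- c(gene, k)
        instance <- c(instance, i); site <- c(site, s)
      }
    }
  }
  data.frame(kind = kind, rxn = rxn, gene = gene, instance = instance,
             site = site, class = class, value = value,
             stringsAsFactors = FALSE)
}

#' Propensities split by volume-scaling class
#'
#' Evaluates every channel at the state's current time and volume:
#' bimolecular channels contribute `k X1 X2 / Omega(t)`
#' (`k X (X - 1) / Omega(t)` for identical reactants), first-order
#' channels `k X`, zeroth-order channels `k` or `k Omega(t)` by class, and
#' each gene instance a transcription channel
#' `a * prod(occupied-site factors)` plus one binding or unbinding channel
#' per site. Channels flagged for extrinsic noise are scaled by
#' `exp(eta)`.
#'
#' @param state a `cell_state` (any negative count is an
#'   internal-consistency failure and raises an error).
#' @param model a `grow_model`.
#' @return A list with totals `A` (volume-independent, 1/s), `b`
#'   (inverse-volume), `g` (proportional-volume) and the per-channel table
#'   `channels` (whose `value` column sums to `A + b + g`).
#' @export
compute_propensities <- function(state, model) {
  stopifnot(inherits(state, "cell_state"))
  if (any(state$counts < 0))
    stop("internal-consistency failure: negative molecule count")
  cm <- if (inherits(model, "grow_model")) compile_model(model) else model
  ch <- enumerate_channels(state, cm, cell_volume(state))
  list(A = sum(ch$value[ch$class == "A"]),
       b = sum(ch$value[ch$class == "b"]),
       g = sum(ch$value[ch$class == "g"]),
       channels = ch)
}

#' Select the reaction channel that fires
#'
#' Re-evaluates all propensities at the firing time `t_fire` (so
#' volume-dependent terms use `V(t_fire)`) and returns the channel whose
#' cumulative propensity first reaches `r2 * total`.
#'
#' @param state a `cell_state`.
#' @param model a `grow_model`.
#' @param t_fire absolute firing time in seconds.
#' @param r2 uniform(0,1) draw.
#' @return One row of the channel table (see [compute_propensities()]).
#' @export
select_channel <- function(state, model, t_fire, r2) {
  cm <- if (inherits(model, "grow_model")) compile_model(model) else model
  ch <- enumerate_channels(state, cm, cell_volume(state, t_fire))
  tot <- sum(ch$value)
  if (tot <= 0) stop("select_channel: total propensity is zero")
  cum <- cumsum(ch$value)
  j <- which(cum >= r2 * tot & ch$value > 0)[1L]
  if (is.na(j)) j <- max(which(ch$value > 0))
  ch[j, , drop = FALSE]
}

#' Execute one reaction channel
#'
#' Instantaneous channels apply their net stoichiometry immediately.
#' Delayed channels consume their net reactants now and enqueue the net
#' products for release `delay` seconds later; species listed with equal
#' stoichiometry on both sides (catalytic templates, e.g. the mRNA in
#' translation) are never touched. Promoter binding channels move one TF
#' molecule from the free pool onto the specific gene instance;
#' unbinding returns it.
#'
#' @param state a `cell_state`.
#' @param channel a channel row from [select_channel()].
#' @param model a `grow_model`.
#' @return The updated `cell_state`.
#' @export
fire_reaction <- function(state, channel, model) {
  cm <- if (inherits(model, "grow_model")) compile_model(model) else model
  kind <- channel$kind[1L]
  t <- state$t
  if (kind == "reaction") {
    j <- channel$rxn[1L]
    cs <- cm$consume[[j]]
    if (length(cs$idx)) {
      ii <- cs$idx + 1L
      state$counts[ii] <- state$counts[ii] - cs$n
      if (any(state$counts[ii] < 0))
        stop("internal error: insufficient reactants for '", cm$sp[ii], "'")
    }
    if (cm$delay[j] > 0) {
      state$queue <- rbind(state$queue,
                           data.frame(time = t + cm$delay[j], kind = 0L,
                                      idx = j))
    } else {
      rl <- cm$release[[j]]
      if (length(rl$idx))
        state$counts[rl$idx + 1L] <- state$counts[rl$idx + 1L] + rl$n
    }
  } else if (kind == "transcription") {
    k <- channel$gene[1L]
    if (cm$g_delay[k] > 0) {
      state$queue <- rbind(state$queue,
                           data.frame(time = t + cm$g_delay[k], kind = 1L,
                                      idx = k))
    } else {
      state$counts[cm$g_mrna[k] + 1L] <- state$counts[cm$g_mrna[k] + 1L] + 1L
    }
  } else if (kind == "bind") {
    k <- channel$gene[1L]; i <- channel$instance[1L]; s <- channel$site[1L]
    tf <- cm$g_sites[[k]]$tf[s] + 1L
    if (state$counts[tf] <= 0)
      stop("internal error: binding with no free TF")
    state$counts[tf] <- state$counts[tf] - 1L
    state$genes[[k]]$bound[i, s] <- 1L
  } else if (kind == "unbind") {
    k <- channel$gene[1L]; i <- channel$instance[1L]; s <- channel$site[1L]
    state$genes[[k]]$bound[i, s] <- 0L
    tf <- cm$g_sites[[k]]$tf[s] + 1L
    state$counts[tf] <- state$counts[tf] + 1L
  } else stop("unknown channel kind: ", kind)
  state
}

#' Execute a gene-replication event
#'
#' Doubles the instance count of one gene: every existing instance gains a
#' newborn sister copy with an unoccupied promoter, and any TF bound to a
#' replicated instance is released to the free pool (the fork displaces
#' it). Existing copies are tagged chromosome 1 and the new sisters
#' chromosome 2, which is how [divide()] hands each daughter an equal
#' complement.
#'
#' @param state a `cell_state`.
#' @param gene gene name or index.
#' @param model a `grow_model`.
#' @return The updated `cell_state`.
#' @export
apply_replication <- function(state, gene, model) {
  k <- if (is.character(gene)) match(gene, names(state$genes)) else gene
  if (is.na(k) || k < 1L || k > length(state$genes))
    stop("unknown gene: ", gene)
  cm <- if (inherits(model, "grow_model")) compile_model(model) else model
  gs <- state$genes[[k]]
  ns <- ncol(gs$bound)
  ni <- nrow(gs$bound)
  if (ns > 0) {
    for (s in seq_len(ns)) {
      nb <- sum(gs$bound[, s])
      if (nb > 0) {
        tf <- cm$g_sites[[k]]$tf[s] + 1L
        state$counts[tf] <- state$counts[tf] + nb
      }
    }
  }
  state$genes[[k]]$bound <- matrix(0L, nrow = 2L * ni, ncol = ns)
  state$genes[[k]]$tag <- c(rep(1L, ni), rep(2L, ni))
  state
}

# sort the pending queue the way the C++ engine orders events:
# time, then releases before replications (all queue entries here are
# releases), then FIFO
sort_queue <- function(q) {
  if (!nrow(q)) return(q)
  q[order(q$time, seq_len(nrow(q))), , drop = FALSE]
}

#' Simulate one cell until division (or the horizon)
#'
#' The event loop of the growth-aware SSA: compute class-split
#' propensities, sample the waiting time exactly under exponential volume
#' growth, and either execute the earliest scheduled event (delayed
#' product release or gene replication — after which the waiting time is
#' resampled; ties run releases first) or fire the sampled channel.
#' The cell runs from its current time to
#' `min(t_birth + T, t_end)`; a replication falling exactly on the
#' division time executes immediately before the cell is returned.
#'
#' @param state a `cell_state` from [new_cell_state()] (or a daughter from
#'   [divide()]).
#' @param model a `grow_model`.
#' @param config a [run_config()].
#' @param t_end optional absolute horizon in seconds (defaults to
#'   `config$t_end`).
#' @param method `"compiled"` (C++ engine) or `"R"` (pure-R reference
#'   stepper; identical trajectories under the same seed, orders of
#'   magnitude slower).
#' @return A list: `trajectory` (data.frame on the output grid: `time_s`,
#'   `volume_L`, one column per species, `copies_<gene>` per gene),
#'   `state` (final `cell_state`), `n_events` (reaction firings),
#'   `divided` (TRUE if the cell reached its division time).
#' @export
run_cell <- function(state, model, config, t_end = NULL,
                     method = c("compiled", "R")) {
  method <- match.arg(method)
  stopifnot(inherits(state, "cell_state"), inherits(model, "grow_model"),
            inherits(config, "run_config"))
  if (is.null(t_end)) t_end <- config$t_end
  t_div <- state$t_birth + state$T_s
  t_stop <- min(t_div, t_end)
  if (!is.finite(t_stop) || t_stop < state$t)
    stop("non-finite or past stopping time")
  cm <- compile_model_noise(model, config)
  if (t_stop == state$t) {  # newborn at the horizon: record-only
    traj <- data.frame(time_s = state$t, volume_L = cell_volume(state))
    traj <- cbind(traj, as.data.frame(t(state$counts)))
    if (cm$ng > 0) {
      cp <- t(vapply(state$genes, function(g) nrow(g$bound), 0L))
      colnames(cp) <- paste0("copies_", cm$g_names)
      traj <- cbind(traj, as.data.frame(cp))
    }
    return(list(trajectory = traj, state = state, n_events = 0,
                divided = FALSE))
  }
  sched <- replication_schedule(model$genes, config$periods,
                                t_birth = state$t_birth / 60,
                                t_end = t_stop / 60,
                                include_end = t_stop == t_div)
  sched <- sched[sched$time * 60 >= state$t, , drop = FALSE]  # resumed cells
  grid <- seq(state$t, t_stop, by = config$grid_dt)
  if (grid[length(grid)] < t_stop) grid <- c(grid, t_stop)
  nz <- config$noise
  ou_tau <- if (is.null(nz)) 1 else nz$tau_c
  ou_sigma <- if (is.null(nz)) 0 else nz$sigma
  q <- sort_queue(state$queue)
  if (method == "compiled") {
    res <- cpp_run_cell(cm, unname(state$counts),
                        lapply(state$genes, `[[`, "bound"),
                        lapply(state$genes, `[[`, "tag"),
                        state$t, t_stop, state$t_birth, state$T_s,
                        state$V_birth, sched$time * 60,
                        as.integer(sched$gene_index - 1L),
                        q$time, as.integer(q$kind), as.integer(q$idx - 1L),
                        grid, ou_tau, ou_sigma, state$eta)
  } else {
    res <- run_cell_r(cm, state, t_stop, sched, grid, ou_tau, ou_sigma)
  }
  traj <- data.frame(time_s = grid,
                     volume_L = state$V_birth *
                       2^((grid - state$t_birth) / state$T_s))
  cmat <- res$counts; colnames(cmat) <- cm$sp
  traj <- cbind(traj, as.data.frame(cmat))
  if (cm$ng > 0) {
    gmat <- res$copies
    colnames(gmat) <- paste0("copies_", cm$g_names)
    traj <- cbind(traj, as.data.frame(gmat))
  }
  fin <- state
  fin$t <- t_stop
  fin$counts[] <- res$final_counts
  for (k in seq_along(fin$genes)) {
    fb <- res$final_bound[[k]]
    if (is.null(dim(fb))) fb <- matrix(as.integer(fb), ncol = 0)
    fin$genes[[k]]$bound <- fb
    fin$genes[[k]]$tag <- res$final_tag[[k]]
  }
  fin$queue <- if (length(res$pend_time))
    data.frame(time = res$pend_time, kind = as.integer(res$pend_kind),
               idx = as.integer(res$pend_idx) + 1L)
  else empty_queue()
  fin$eta <- res$eta
  list(trajectory = traj, state = fin, n_events = res$n_events,
       divided = t_div <= t_end)
}

# compile + apply the noise block's applied_to flags
compile_model_noise <- function(model, config) {
  cm <- compile_model(model)
  nz <- config$noise
  if (!is.null(nz) && length(nz$applied_to)) {
    rx <- vapply(model$reactions, `[[`, "", "name")
    cm$noise <- cm$noise | rx %in% nz$applied_to
    cm$g_noise <- cm$g_noise | cm$g_names %in% nz$applied_to
  }
  cm
}

# Pure-R event loop, RNG-draw-for-draw identical to cpp_run_cell: used as
# the readable reference semantics and cross-checked bit-for-bit in the
# test suite.
run_cell_r <- function(cm, state, t_stop, sched, grid, ou_tau, ou_sigma) {
  mu <- log(2) / state$T_s
  ou_active <- ou_sigma > 0 || state$eta != 0
  events <- rbind(
    if (nrow(state$queue))
      data.frame(time = state$queue$time, prio = 0L,
                 kind = state$queue$kind, idx = state$queue$idx)
    else NULL,
    if (nrow(sched))
      data.frame(time = sched$time * 60, prio = 1L, kind = 2L,
                 idx = sched$gene_index)
    else NULL)
  if (is.null(events))
    events <- data.frame(time = numeric(0), prio = integer(0),
                         kind = integer(0), idx = integer(0))
  events <- events[order(events$time, events$prio, seq_len(nrow(events))), ,
                   drop = FALSE]
  ngrid <- length(grid)
  out_counts <- matrix(0L, ngrid, cm$nsp)
  out_copies <- matrix(0L, ngrid, max(cm$ng, 1L))
  gidx <- 0L
  record_upto <- function(tnew) {
    while (gidx < ngrid && grid[gidx + 1L] <= tnew) {
      gidx <<- gidx + 1L
      out_counts[gidx, ] <<- unname(state$counts)
      if (cm$ng > 0)
        out_copies[gidx, ] <<- vapply(state$genes, function(g)
          nrow(g$bound), 0L)
    }
  }
  ou_update <- function(dt) {
    if (!ou_active || dt <= 0) return()
    state$eta <<- state$eta * exp(-dt / ou_tau)
    if (ou_sigma > 0)
      state$eta <<- state$eta +
        ou_sigma * sqrt(-expm1(-2 * dt / ou_tau)) * stats::rnorm(1)
  }
  # sequential 64-bit summation, matching the C++ accumulator exactly
  # (R's sum() accumulates in extended precision and drifts by ULPs)
  sum_seq <- function(x) {
    s <- 0
    for (v in x) s <- s + v
    s
  }
  record_upto(state$t)
  nev <- 0
  while (state$t < t_stop) {
    V <- cell_volume(state)
    ch <- enumerate_channels(state, cm, V)
    A <- sum_seq(ch$value[ch$class == "A"])
    b <- sum_seq(ch$value[ch$class == "b"])
    g <- sum_seq(ch$value[ch$class == "g"])
    r1 <- stats::runif(1)
    tau <- cpp_sample_firing_time(A, b, g, mu, r1)
    t_cand <- if (is.finite(tau)) state$t + tau else Inf
    have_ev <- nrow(events) > 0 && events$time[1L] <= t_stop
    if (have_ev && events$time[1L] <= t_cand) {
      ev <- events[1L, ]
      events <- events[-1L, , drop = FALSE]
      record_upto(ev$time)
      ou_update(ev$time - state$t)
      state$t <- ev$time
      if (ev$kind == 0L) {
        rl <- cm$release[[ev$idx]]
        if (length(rl$idx))
          state$counts[rl$idx + 1L] <- state$counts[rl$idx + 1L] + rl$n
      } else if (ev$kind == 1L) {
        state$counts[cm$g_mrna[ev$idx] + 1L] <-
          state$counts[cm$g_mrna[ev$idx] + 1L] + 1L
      } else {
        gs <- state$genes[[ev$idx]]
        ni <- nrow(gs$bound); ns <- ncol(gs$bound)
        if (ns > 0)
          for (s in seq_len(ns)) {
            nb <- sum(gs$bound[, s])
            if (nb > 0) {
              tf <- cm$g_sites[[ev$idx]]$tf[s] + 1L
              state$counts[tf] <- state$counts[tf] + nb
            }
          }
        state$genes[[ev$idx]]$bound <- matrix(0L, 2L * ni, ns)
        state$genes[[ev$idx]]$tag <- c(rep(1L, ni), rep(2L, ni))
      }
      next
    }
    if (t_cand > t_stop) {
      record_upto(t_stop)
      ou_update(t_stop - state$t)
      state$t <- t_stop
      break
    }
    record_upto(t_cand)
    dt <- t_cand - state$t
    state$t <- t_cand
    Vf <- cell_volume(state)
    ch2 <- enumerate_channels(state, cm, Vf)
    tot <- sum_seq(ch2$value[ch2$class == "A"]) +
      sum_seq(ch2$value[ch2$class == "b"]) +
      sum_seq(ch2$value[ch2$class == "g"])
    r2 <- stats::runif(1)
    if (tot > 0) {
      cum <- cumsum(ch2$value)
      j <- which(cum >= r2 * tot & ch2$value > 0)[1L]
      if (is.na(j)) j <- max(which(ch2$value > 0))
      chosen <- ch2[j, , drop = FALSE]
      if (chosen$kind == "reaction" && cm$delay[chosen$rxn] > 0) {
        cs <- cm$consume[[chosen$rxn]]
        if (length(cs$idx))
          state$counts[cs$idx + 1L] <- state$counts[cs$idx + 1L] - cs$n
        if (any(state$counts < 0)) stop("negative count")
        events <- rbind(events,
                        data.frame(time = state$t + cm$delay[chosen$rxn],
                                   prio = 0L, kind = 0L, idx = chosen$rxn))
        events <- events[order(events$time, events$prio,
                               seq_len(nrow(events))), , drop = FALSE]
      } else if (chosen$kind == "transcription" &&
                 cm$g_delay[chosen$gene] > 0) {
        events <- rbind(events,
                        data.frame(time = state$t + cm$g_delay[chosen$gene],
                                   prio = 0L, kind = 1L, idx = chosen$gene))
        events <- events[order(events$time, events$prio,
                               seq_len(nrow(events))), , drop = FALSE]
      } else {
        state <- fire_reaction(state, chosen, cm)
      }
      nev <- nev + 1
    }
    ou_update(dt)
  }
  # drain events scheduled exactly at the stopping time (mirrors C++)
  while (nrow(events) && events$time[1L] <= t_stop) {
    ev <- events[1L, ]
    events <- events[-1L, , drop = FALSE]
    if (ev$kind == 0L) {
      rl <- cm$release[[ev$idx]]
      if (length(rl$idx))
        state$counts[rl$idx + 1L] <- state$counts[rl$idx + 1L] + rl$n
    } else if (ev$kind == 1L) {
      state$counts[cm$g_mrna[ev$idx] + 1L] <-
        state$counts[cm$g_mrna[ev$idx] + 1L] + 1L
    } else {
      gs <- state$genes[[ev$idx]]
      ni <- nrow(gs$bound); ns <- ncol(gs$bound)
      if (ns > 0)
        for (s in seq_len(ns)) {
          nb <- sum(gs$bound[, s])
          if (nb > 0) {
            tf <- cm$g_sites[[ev$idx]]$tf[s] + 1L
            state$counts[tf] <- state$counts[tf] + nb
          }
        }
      state$genes[[ev$idx]]$bound <- matrix(0L, 2L * ni, ns)
      state$genes[[ev$idx]]$tag <- c(rep(1L, ni), rep(2L, ni))
    }
  }
  record_upto(t_stop)
  pend <- events[events$kind != 2L, , drop = FALSE]
  list(counts = out_counts,
       copies = out_copies[, seq_len(cm$ng), drop = FALSE],
       final_counts = unname(state$counts),
       final_bound = lapply(state$genes, `[[`, "bound"),
       final_tag = lapply(state$genes, `[[`, "tag"),
       pend_time = pend$time, pend_kind = pend$kind, pend_idx = pend$idx,
       n_events = nev, eta = state$eta)
}
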