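# Independent reference solvers: deterministic ODE / delay-ODE for the
# negative-autoregulation circuit, a classic constant-volume SSA, and the
# deterministic dynamic flux-balance model. These are oracles for the
# growth-aware engine and share none of its code paths.

#' Parameter set of the negative-autoregulation circuit
#'
#' Defaults are the printed rates of the autoregulation system:
#' transcription `a` = 1 /gene/s, translation `b` = 1 /mRNA/s, mRNA
#' degradation `r1` = 2 /s, protein decay `r2` = 0.01 /s, dimer
#' production `c` = 1 (read as per-uM-per-second; see the methods
#' vignette for the unit discussion) and dissociation `d` = 1 /s,
#' promoter binding `K1` = 100 per-uM-per-second and unbinding
#' `K2` = 0.1 /s; a bound dimer lowers transcription 10-fold
#' (`rep_factor` = 0.1).
#'
#' @param a,b,r1,r2,c,d,K1,K2,rep_factor rate constants as above.
#' @return Named numeric vector.
#' @export
autoreg_params <- function(a = 1, b = 1, r1 = 2, r2 = 0.01, c = 1, d = 1,
                           K1 = 100, K2 = 0.1, rep_factor = 0.1) {
  c(a = a, b = b, r1 = r1, r2 = r2, c = c, d = d, K1 = K1, K2 = K2,
    fac = rep_factor)
}

#' Deterministic ODE for the negative-autoregulation circuit
#'
#' Concentrations in uM; state (mRNA `m`, protein `P`, dimer `dm`, bound
#' promoter `Gb`, with free promoter `Gf = G0 - Gb`):
#' \deqn{dm/dt = a (Gf + 0.1 Gb) - r_1 m}
#' \deqn{dP/dt = b m - r_2 P - 2 c P^2 + 2 d \cdot dm}
#' \deqn{d(dm)/dt = c P^2 - d \cdot dm - K_1 dm \cdot Gf + K_2 Gb}
#' \deqn{dGb/dt = K_1 dm \cdot Gf - K_2 Gb}
#' Promoter-bound dimer is booked separately from the free dimer pool.
#' All initial values are zero. Fixed-step RK4.
#'
#' @param params from [autoreg_params()].
#' @param gene_dosage_uM total promoter concentration `G0`; 0.003 uM is
#'   about two gene copies in a 1.1e-15 L cell.
#' @param t_end horizon in seconds.
#' @param h RK4 step (s).
#' @param out_dt output grid (s).
#' @param y0 initial state (uM), default all zero.
#' @return data.frame `time_s`, `mRNA`, `protein`, `dimer`,
#'   `bound_promoter` (uM); attribute `clipped` counts negative
#'   excursions clipped to zero.
#' @export
integrate_autoreg_ode <- function(params = autoreg_params(),
                                  gene_dosage_uM = 0.003, t_end = 24000,
                                  h = 0.01, out_dt = 10,
                                  y0 = c(0, 0, 0, 0)) {
  stopifnot(all(params > 0), gene_dosage_uM > 0, t_end > 0, h > 0)
  res <- cpp_autoreg_ode(params, gene_dosage_uM, y0, 0, t_end, h, out_dt)
  fmt_autoreg(res)
}

fmt_autoreg <- function(res) {
  s <- res$series[seq_len(res$nout), , drop = FALSE]
  out <- data.frame(time_s = s[, 1], mRNA = s[, 2], protein = s[, 3],
                    dimer = s[, 4], bound_promoter = s[, 5])
  attr(out, "clipped") <- res$clipped
  attr(out, "h") <- res$h
  out
}

#' Steady state of the autoregulation ODE
#'
#' Integrates until the relative change over a 100 s window drops below
#' `tol` (default 1e-8), then reports the state.
#'
#' @inheritParams integrate_autoreg_ode
#' @param tol convergence tolerance.
#' @param t_max give up beyond this horizon.
#' @return Named vector (uM) with attribute `t_converged`.
#' @export
autoreg_steady_state <- function(params = autoreg_params(),
                                 gene_dosage_uM = 0.003, h = 0.01,
                                 tol = 1e-8, t_max = 2e5) {
  y <- c(0, 0, 0, 0)
  t <- 0
  chunk <- 2000
  repeat {
    res <- cpp_autoreg_ode(params, gene_dosage_uM, y, 0, chunk, h, 100)
    s <- res$series[seq_len(res$nout), , drop = FALSE]
    n <- nrow(s)
    y_new <- s[n, 2:5]
    y_prev <- s[n - 1L, 2:5]
    t <- t + chunk
    rel <- max(abs(y_new - y_prev) / pmax(abs(y_new), 1e-12))
    y <- y_new
    if (rel < tol || t >= t_max) break
  }
  if (rel >= tol) warning("steady state not reached by t_max")
  out <- c(mRNA = y[1], protein = y[2], dimer = y[3], bound_promoter = y[4])
  attr(out, "t_converged") <- t
  out
}

#' Delay-ODE for the autoregulation circuit with delayed translation
#'
#' Same right-hand side as [integrate_autoreg_ode()] but with the
#' translation term `b * m(t - delay)`: the multi-step synthesis of the
#' protein is compressed into a fixed lag. Integrated with fixed-step RK4
#' and cubic-Hermite interpolation of the mRNA history; the step is
#' forced to at most `delay/20` (a step larger than the delay is
#' rejected). A sufficiently long delay destabilises the negative
#' feedback and produces limit-cycle oscillations.
#'
#' @inheritParams integrate_autoreg_ode
#' @param delay translation delay in seconds; `delay = 0` falls back to
#'   the plain ODE.
#' @return As [integrate_autoreg_ode()].
#' @export
integrate_delayed_ode <- function(params = autoreg_params(),
                                  gene_dosage_uM = 0.003, delay = 1000,
                                  t_end = 24000, h = 0.01, out_dt = 10,
                                  y0 = c(0, 0, 0, 0)) {
  stopifnot(delay >= 0, t_end > 0, h > 0)
  if (delay == 0)
    return(integrate_autoreg_ode(params, gene_dosage_uM, t_end, h, out_dt,
                                 y0))
  if (h > delay)
    stop("integration step larger than the delay")
  h <- min(h, delay / 20)   # history interpolation needs >= 20 nodes/lag
  res <- cpp_autoreg_ode(params, gene_dosage_uM, y0, delay, t_end, h,
                         out_dt)
  fmt_autoreg(res)
}

#' Classic constant-volume Gillespie SSA
#'
#' Direct-method SSA at fixed volume on a flat reaction model (no genes,
#' no delays, no growth, no division) — the standard against which the
#' growth-aware engine is validated in the zero-growth limit. Models with
#' genes can be converted first with [flatten_gene_model()].
#'
#' @param model a `grow_model` without genes or delayed reactions.
#' @param t_end horizon in seconds.
#' @param V constant cell volume in litres.
#' @param grid_dt output grid step (s).
#' @return A list: `trajectory` data.frame (`time_s`, one column per
#'   species), `final_counts`, `n_events`.
#' @export
classic_ssa <- function(model, t_end, V = 1.1e-15, grid_dt = 1) {
  stopifnot(inherits(model, "grow_model"))
  if (length(model$genes))
    stop("classic_ssa takes a flat model; use flatten_gene_model() first")
  if (any(vapply(model$reactions, `[[`, 0, "delay") > 0))
    stop("classic_ssa does not support delayed reactions")
  cm <- compile_model(model)
  grid <- seq(0, t_end, by = grid_dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  res <- cpp_classic_ssa(unname(vapply(model$species, `[[`, 0L,
                                       "initial_count")),
                         cm$ord, cm$ri1, cm$ri2, cm$vclass, cm$kappa,
                         cm$mm_e, cm$mm_s, cm$mm_KmNA, cm$consume,
                         cm$release, V, 0, t_end, grid)
  traj <- data.frame(time_s = grid)
  cmat <- res$counts; colnames(cmat) <- cm$sp
  traj <- cbind(traj, as.data.frame(cmat))
  fc <- res$final_counts; names(fc) <- cm$sp
  list(trajectory = traj, final_counts = fc, n_events = res$n_events)
}

#' Flatten genes into explicit promoter-state species
#'
#' Rewrites each single-binding-site gene as two species
#' `<gene>_free` / `<gene>_bound` with mass-action transcription from
#' each state, TF binding (`TF + free -> bound`) and unbinding — the
#' representation a flat SSA needs. Exchangeability of gene instances
#' makes this exactly equivalent to the per-instance bookkeeping of the
#' engine at fixed copy number.
#'
#' @param model a `grow_model`.
#' @param periods optional [cycle_periods()] used to fill copy numbers for
#'   genes without an `initial_copies` override.
#' @return A flat `grow_model` (no genes).
#' @export
flatten_gene_model <- function(model, periods = NULL) {
  stopifnot(inherits(model, "grow_model"))
  species <- model$species
  reactions <- model$reactions
  for (g in model$genes) {
    if (length(g$sites) > 1L)
      stop("flatten_gene_model supports promoters with at most one site")
    copies <- if (!is.null(g$initial_copies)) g$initial_copies
    else if (!is.null(periods)) copies_at_birth(g$position, periods)
    else stop(sprintf("gene '%s': no initial_copies and no periods given",
                      g$name))
    gf <- paste0(g$name, "_free")
    species <- c(species, list(
      species_def(gf, copies, partition_at_division = FALSE)))
    tx_args <- list(name = paste0("tx_", g$name),
                    reactants = stats::setNames(1L, gf),
                    products = stats::setNames(c(1L, 1L), c(gf, g$mrna)),
                    rate = g$rate, delay = g$delay)
    reactions <- c(reactions, list(do.call(reaction_def, tx_args)))
    if (length(g$sites) == 1L) {
      s <- g$sites[[1L]]
      gb <- paste0(g$name, "_bound")
      species <- c(species, list(
        species_def(gb, 0L, partition_at_division = FALSE)))
      reactions <- c(reactions, list(
        reaction_def(paste0("tx_", g$name, "_repressed"),
                     reactants = stats::setNames(1L, gb),
                     products = stats::setNames(c(1L, 1L), c(gb, g$mrna)),
                     rate = g$rate * s$factor, delay = g$delay),
        reaction_def(paste0("bind_", g$name),
                     reactants = stats::setNames(c(1L, 1L), c(s$tf, gf)),
                     products = stats::setNames(1L, gb),
                     rate = s$kon, volume_class = "inverse-volume"),
        reaction_def(paste0("unbind_", g$name),
                     reactants = stats::setNames(1L, gb),
                     products = stats::setNames(c(1L, 1L), c(gf, s$tf)),
                     rate = s$koff)))
    }
  }
  build_model(list(species = species, reactions = reactions))
}

#' Parameter set of the metabolic flux model
#'
#' Defaults are the printed rates of the metabolic system: M1 uptake
#' `influx` = 100 uM/s, M1/M3 utilisation `r3` = 1 /s, mRNA degradation
#' `r1` = 1 /s, enzyme decay `r2` = 0.01 /s, catalytic constant
#' `Kc` = 10 /s, `Km` = 1 uM, transcription `a` = 1 /gene/s,
#' translation `b` = 1 /mRNA/s, and dilution `mu` = ln(2)/T per second
#' for a 50-minute generation (printed as 0.0139 per minute).
#'
#' @param influx,r3,r1,r2,Kc,Km,a,b rates as above.
#' @param T_min generation time in minutes (sets `mu`).
#' @return Named numeric vector (rates per second).
#' @export
flux_params <- function(influx = 100, r3 = 1, r1 = 1, r2 = 0.01, Kc = 10,
                        Km = 1, a = 1, b = 1, T_min = 50) {
  c(influx = influx, r3 = r3, r1 = r1, r2 = r2, Kc = Kc, Km = Km, a = a,
    b = b, mu = log(2) / (T_min * 60))
}

#' Deterministic dynamic flux-balance model
#'
#' Michaelis-Menten fluxes between three metabolites with
#' gene-dosage-driven enzyme synthesis:
#' M1 is taken up at a constant concentration flux, enzyme a converts
#' M1 -> M2 and enzyme b converts M2 -> M3 (both
#' `Kc E S / (Km + S)`), M1 and M3 are additionally utilised at `r3`,
#' and every species is diluted at `mu`. Transcription follows the
#' deterministic Cooper-Helmstetter dosage step function of each gene's
#' chromosomal position, which is how the position effect enters the
#' deterministic model.
#'
#' @param params from [flux_params()].
#' @param positions length-2 numeric, chromosome positions of gene a and
#'   gene b.
#' @param periods a [cycle_periods()].
#' @param omega_ref molecules per uM used to express dosage and initial
#'   counts as concentrations (default: a 1.1e-15 L birth volume).
#' @param t_end horizon (s).
#' @param h RK4 step (s).
#' @param out_dt output grid (s).
#' @param init_counts named counts for `M1`, `M2`, `M3`, `mRNA`, `enzyme`
#'   (the printed initial condition: metabolites 50 molecules, enzymes
#'   100, mRNAs 10).
#' @param transcription optional length-2 per-gene transcription rates
#'   overriding `params["a"]` (e.g. `c(1, 0)` switches enzyme b's gene
#'   off entirely).
#' @return data.frame `time_s`, `M1`, `M2`, `M3`, `mRNA_a`, `enz_a`,
#'   `mRNA_b`, `enz_b`, `dosage_a`, `dosage_b` (uM).
#' @export
integrate_flux_ode <- function(params = flux_params(),
                               positions = c(0.5, 0.5),
                               periods = cycle_periods(T = 50),
                               omega_ref = omega_factor(1.1e-15),
                               t_end = 18000, h = 0.02, out_dt = 10,
                               init_counts = c(M1 = 50, M2 = 50, M3 = 50,
                                               mRNA = 10, enzyme = 100),
                               transcription = NULL) {
  stopifnot(length(positions) == 2L, t_end > 0, h > 0)
  periods <- as_periods(periods)
  # dosage breakpoints: birth and replication age of each gene, per cycle
  T_s <- periods$T * 60
  ncyc <- ceiling(t_end / T_s)
  bp <- sort(unique(c(
    0, as.vector(outer((0:ncyc) * T_s,
                       replication_age(positions, periods) * 60, `+`)))))
  bp <- bp[bp <= t_end]
  dos <- function(p) vapply(bp, function(tt) {
    age <- (tt / 60) %% periods$T
    copies_at_age(p, periods, age) / omega_ref
  }, 0)
  y0 <- c(init_counts[["M1"]], init_counts[["M2"]], init_counts[["M3"]],
          init_counts[["mRNA"]], init_counts[["enzyme"]],
          init_counts[["mRNA"]], init_counts[["enzyme"]]) / omega_ref
  # per-gene transcription overrides fold into the dosage step function
  # (the RHS multiplies a * dosage)
  sc <- if (is.null(transcription)) c(1, 1)
        else transcription / params[["a"]]
  res <- cpp_flux_ode(params, y0, bp, dos(positions[1L]) * sc[1L],
                      dos(positions[2L]) * sc[2L], t_end, h, out_dt)
  s <- res$series[seq_len(res$nout), , drop = FALSE]
  out <- data.frame(time_s = s[, 1], M1 = s[, 2], M2 = s[, 3], M3 = s[, 4],
                    mRNA_a = s[, 5], enz_a = s[, 6], mRNA_b = s[, 7],
                    enz_b = s[, 8], dosage_a = s[, 9], dosage_b = s[, 10])
  attr(out, "clipped") <- res$clipped
  out
}

#' Oscillation score of a time series
#'
#' High-passes the series (subtracting a centred running mean over
#' `window` seconds, which removes cell-cycle-scale dosage and volume
#' trends) and returns the minimum of the autocorrelation function over
#' lags up to `max_lag` seconds. Sustained oscillations with period
#' `< 2 * max_lag` give a pronounced negative minimum (the score);
#' `score < -0.3` is the detection criterion used by the packaged
#' examples. Near-constant series score 0.
#'
#' @param time,x numeric vectors on a uniform grid (seconds).
#' @param burn initial transient to discard (s).
#' @param window running-mean width of the high-pass (s).
#' @param max_lag largest autocorrelation lag examined (s).
#' @return The minimum autocorrelation (numeric scalar) with attribute
#'   `lag_s` (the lag where it is attained).
#' @export
oscillation_score <- function(time, x, burn = 2000, window = 5000,
                              max_lag = 5000) {
  stopifnot(length(time) == length(x), length(x) > 10)
  keep <- time >= (time[1] + burn)
  time <- time[keep]; x <- x[keep]
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("oscillation_score needs a uniform time grid")
  dt <- dt[1]
  k <- max(3L, 2L * floor(window / dt / 2) + 1L)  # odd window
  if (k >= length(x)) stop("series shorter than the high-pass window")
  trend <- stats::filter(x, rep(1 / k, k), sides = 2)
  hp <- (x - trend)[!is.na(trend)]
  if (stats::sd(hp) < 1e-10 * (1 + abs(mean(x))))
    return(structure(0, lag_s = NA_real_))
  nl <- min(floor(max_lag / dt), length(hp) - 2L)
  ac <- stats::acf(hp, lag.max = nl, plot = FALSE, demean = TRUE)$acf[-1]
  structure(min(ac), lag_s = which.min(ac) * dt)
}
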