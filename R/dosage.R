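#' Cell-cycle periods for the Cooper-Helmstetter replication schedule
#'
#' Bundles the three deterministic timing constants of the bacterial cell
#' cycle: the generation time `T`, the chromosome replication time `C`
#' (fork travel from origin to terminus, classically ~40 min in
#' *E. coli*), and the `D` period between replication termination and
#' division (~20 min). When `C + D > T` the cell runs overlapping
#' replication rounds: a round destined for a daughter (or granddaughter)
#' starts in the mother, and a locus can be present in up to
#' `2^(floor((C*(1-p)+D)/T)+1)` simultaneous copies.
#'
#' @param T generation time in minutes.
#' @param C replication (fork travel) time in minutes, default 40.
#' @param D post-termination division delay in minutes, default 20.
#' @return An object of class `cycle_periods`.
#' @examples
#' cycle_periods(T = 50)          # fast growth, C + D > T
#' cycle_periods(T = 200)         # slow growth, non-overlapping cycles
#' @export
cycle_periods <- function(T, C = 40, D = 20) {
  stopifnot(is.numeric(T), is.numeric(C), is.numeric(D),
            length(T) == 1L, length(C) == 1L, length(D) == 1L)
  if (!all(is.finite(c(T, C, D))) || T <= 0 || C <= 0 || D <= 0)
    stop("cycle periods T, C, D must be finite and > 0")
  structure(list(T = T, C = C, D = D), class = "cycle_periods")
}

#' @export
print.cycle_periods <- function(x, ...) {
  cat(sprintf("cell-cycle periods: T = %g min, C = %g min, D = %g min\n",
              x$T, x$C, x$D))
  cat(sprintf("  overlapping cycles: %s (C + D = %g min)\n",
              if (x$C + x$D > x$T) "yes" else "no", x$C + x$D))
  invisible(x)
}

as_periods <- function(periods) {
  if (inherits(periods, "cycle_periods")) return(periods)
  if (is.list(periods)) return(cycle_periods(periods$T, periods$C, periods$D))
  stop("`periods` must be a cycle_periods object or a list with T, C, D")
}

check_position <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("gene position p must be finite and within [0, 1]")
  p
}

#' Cell age at which a gene's copy number doubles
#'
#' Under the deterministic Cooper-Helmstetter schedule, a replication fork
#' needs `C*(1-p)` minutes after passing locus `p` to reach the terminus,
#' plus `D` minutes until the division that the round triggers. Counting
#' backwards, the fork passes `p` exactly `C*(1-p) + D` minutes before a
#' division, i.e. at cell age `T - ((C*(1-p) + D) mod T)`.
#'
#' Boundary convention: when `(C*(1-p) + D)` is an exact multiple of `T`
#' the doubling coincides with division and the function returns `T`
#' (the daughters are born with the pre-doubling per-daughter complement).
#'
#' @param p chromosomal position in `[0, 1]`: 0 = replication origin,
#'   1 = terminus.
#' @param periods a [cycle_periods()] object (or list with `T`, `C`, `D`),
#'   all in minutes.
#' @return Doubling age in minutes, in `(0, T]`.
#' @examples
#' per <- cycle_periods(T = 50, C = 40, D = 20)
#' replication_age(0, per)   # origin gene doubles at age 40 min
#' replication_age(1, per)   # terminus gene doubles at age 30 min
#' @export
replication_age <- function(p, periods) {
  periods <- as_periods(periods)
  check_position(p)
  lead <- periods$C * (1 - p) + periods$D   # fork-passage lead before division
  m <- lead %% periods$T
  age <- ifelse(m == 0, periods$T, periods$T - m)
  age
}

#' Gene copy number at cell birth
#'
#' Each full generation time `T` contained in the pre-division lead
#' `C*(1-p) + D` corresponds to one replication round already past locus
#' `p` at birth, so a newborn carries `2^floor((C*(1-p)+D)/T)` copies.
#'
#' @inheritParams replication_age
#' @return A positive integer power of two.
#' @examples
#' per <- cycle_periods(T = 50)
#' copies_at_birth(0, per)  # 2 copies of an origin-proximal gene
#' copies_at_birth(1, per)  # 1 copy of a terminus-proximal gene
#' @export
copies_at_birth <- function(p, periods) {
  periods <- as_periods(periods)
  check_position(p)
  lead <- periods$C * (1 - p) + periods$D
  as.integer(2^floor(lead / periods$T))
}

#' Gene copy number at a given cell age
#'
#' Right-continuous step function over one cell cycle: the birth copy
#' number until the fork passes the locus at [replication_age()], twice
#' that afterwards.
#'
#' @inheritParams replication_age
#' @param age cell age in minutes, in `[0, T)`.
#' @return Positive integer copy number.
#' @export
copies_at_age <- function(p, periods, age) {
  periods <- as_periods(periods)
  check_position(p)
  if (!is.numeric(age) || any(!is.finite(age)))
    stop("age must be finite")
  if (any(age < 0) || any(age >= periods$T))
    stop("age must lie in [0, T)")
  born <- copies_at_birth(p, periods)
  ifelse(age < replication_age(p, periods), born, 2L * born)
}

#' Population-average gene dosage
#'
#' Expected instantaneous copy number of locus `p` in an exponentially
#' growing population, whose cell-age density is
#' `f(a) = (2 log 2 / T) 2^(-a/T)` on `[0, T)`. The expectation has the
#' classical closed form `2^((C*(1-p)+D)/T)`.
#'
#' @inheritParams replication_age
#' @return Positive real mean dosage.
#' @examples
#' population_mean_dosage(0, cycle_periods(T = 50))    # 2^1.2
#' @export
population_mean_dosage <- function(p, periods) {
  periods <- as_periods(periods)
  check_position(p)
  2^((periods$C * (1 - p) + periods$D) / periods$T)
}

#' Deterministic replication schedule over a simulation horizon
#'
#' For each gene, doubling events fall at
#' `t_birth + replication_age(p) + k*T` (minutes) for `k = 0, 1, ...`.
#' Events are generated strictly inside `[t_birth, t_end)` except that an
#' event coinciding with `t_end` is included when `t_end` is the division
#' time (the engine executes it immediately before division; see
#' [replication_age()] for the boundary convention).
#'
#' @param genes a list of gene definitions (each with `name` and
#'   `position`), e.g. `model$genes` from [build_model()].
#' @param periods a [cycle_periods()] object (minutes).
#' @param t_birth,t_end horizon bounds in minutes; `t_end > t_birth`.
#' @param include_end logical; include events falling exactly at `t_end`
#'   (used by the engine when `t_end` is the division time).
#' @return A data.frame with columns `time` (minutes, ascending; ties
#'   broken by gene declaration order), `gene` (name) and `event`
#'   (`"replication"`).
#' @export
replication_schedule <- function(genes, periods, t_birth, t_end,
                                 include_end = FALSE) {
  periods <- as_periods(periods)
  if (!is.finite(t_birth) || !is.finite(t_end) || t_end <= t_birth)
    stop("need finite t_end > t_birth")
  rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    first <- t_birth + replication_age(g$position, periods)
    if (first > t_end || (first == t_end && !include_end)) next
    ks <- 0:floor((t_end - first) / periods$T)
    tt <- first + ks * periods$T
    tt <- tt[tt < t_end | (include_end & tt == t_end)]
    if (length(tt))
      rows[[length(rows) + 1L]] <-
        data.frame(time = tt, gene = g$name, gene_index = gi,
                   stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(time = numeric(0), gene = character(0),
                      gene_index = integer(0), event = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$time, out$gene_index), , drop = FALSE]
  out$event <- "replication"
  rownames(out) <- NULL
  out
}
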