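# Domain types and validation for species, reactions, genes and promoters.
#
# Unit convention (documented in the methods vignette): all internal state
# is integer molecule counts. Concentrations are micromolar; the conversion
# factor is Omega(t) = N_A * V(t) * 1e-6 molecules per uM for a cell of
# volume V litres. Rate constants expressed in uM units are converted once,
# at model-compile time.

NA_PER_UM <- 6.02214076e17  # Avogadro * 1e-6: molecules per uM per litre

#' Molecules per micromolar for a given cell volume
#'
#' `omega_factor(V)` returns `N_A * V * 1e-6`, the number of molecules in a
#' cell of volume `V` litres at a concentration of 1 uM. For the default
#' birth volume of 1.1e-15 L (typical *E. coli*), Omega is about 662.4.
#'
#' @param V cell volume in litres.
#' @return Molecules per uM.
#' @export
omega_factor <- function(V) NA_PER_UM * V

.known_units <- c("per-second", "per-uM-per-second", "uM-per-second",
                  "per-gene-per-second", "per-mRNA-per-second",
                  "molecules-per-second")
.known_vclasses <- c("volume-independent", "inverse-volume",
                     "proportional-volume")

#' Define a chemical species
#'
#' @param name species identifier (unique within a model).
#' @param initial_count nonnegative integer, molecules per cell at birth.
#' @param partition_at_division logical; free molecules are binomially
#'   partitioned between daughters at division, chromosome-associated
#'   entities are not.
#' @return A `species_def` list.
#' @export
species_def <- function(name, initial_count = 0L,
                        partition_at_division = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(initial_count) || length(initial_count) != 1L ||
      !is.finite(initial_count) || initial_count < 0 ||
      initial_count != round(initial_count))
    stop(sprintf("species '%s': initial_count must be a nonnegative integer",
                 name))
  structure(list(name = name,
                 initial_count = as.integer(initial_count),
                 partition_at_division = isTRUE(partition_at_division)),
            class = "species_def")
}

#' Define a reaction channel
#'
#' Reactions are elementary mass-action channels of order 0, 1 or 2
#' (total reactant stoichiometry), or a Michaelis-Menten conversion
#' (`rate_law = "michaelis_menten"`). Propensities by volume-scaling class:
#' * order 2, `inverse-volume`: `k * X1 * X2 / Omega(t)`
#'   (`k * X * (X-1) / Omega(t)` for identical reactants, the count-based
#'   convention);
#' * order 1, `volume-independent`: `k * X`;
#' * order 0, `volume-independent`: `k` molecules/s per cell;
#' * order 0, `proportional-volume`: `k * Omega(t)` molecules/s for a rate
#'   `k` defined in uM/s (concentration-defined influx);
#' * Michaelis-Menten: `kcat * E * S / (Km * Omega(t) + S)` with `E`, `S`
#'   in molecules and `Km` in uM (quasi-static between events).
#'
#' A positive `delay` makes the channel a delayed reaction: net-consumed
#' reactants are removed at initiation and net products are released
#' `delay` seconds later (catalytic species listed on both sides, such as
#' the mRNA template in translation, are never touched).
#'
#' @param name reaction identifier.
#' @param reactants,products named integer vectors (species -> stoichiometric
#'   count); empty (`c()`/NULL) allowed.
#' @param rate positive rate constant `k`.
#' @param rate_units one of `r toString(.known_units)`; optional,
#'   used for unit-consistency checks.
#' @param volume_class one of `r toString(.known_vclasses)`; defaults by
#'   order (2 -> inverse-volume, otherwise volume-independent).
#' @param delay nonnegative delay in seconds (0 = instantaneous).
#' @param rate_law `"mass_action"` (default) or `"michaelis_menten"`.
#' @param enzyme,substrate,Km Michaelis-Menten fields: enzyme species
#'   (catalytic, not consumed), substrate species (must be the single
#'   reactant), `Km` in uM. `rate` is then `kcat` in 1/s.
#' @param noise logical; if TRUE the rate is modulated by the shared
#'   Ornstein-Uhlenbeck extrinsic-noise process (see [ou_params()]).
#' @return A `reaction_def` list.
#' @export
reaction_def <- function(name, reactants = NULL, products = NULL, rate,
                         rate_units = NULL, volume_class = NULL, delay = 0,
                         rate_law = c("mass_action", "michaelis_menten"),
                         enzyme = NULL, substrate = NULL, Km = NULL,
                         noise = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  rate_law <- match.arg(rate_law)
  as_stoich <- function(x, what) {
    if (is.null(x) || length(x) == 0L) return(integer(0))
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(sprintf("reaction '%s': %s must be a named vector", name, what))
    if (any(x < 1) || any(x != round(x)))
      stop(sprintf("reaction '%s': %s stoichiometries must be positive integers",
                   name, what))
    v <- as.integer(x); names(v) <- names(x)
    tapply_sum <- tapply(v, names(v), sum)          # merge duplicates
    out <- as.integer(tapply_sum); names(out) <- names(tapply_sum)
    out
  }
  reactants <- as_stoich(reactants, "reactants")
  products <- as_stoich(products, "products")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop(sprintf("reaction '%s': rate must be a positive finite number", name))
  if (!is.numeric(delay) || length(delay) != 1L || !is.finite(delay) ||
      delay < 0)
    stop(sprintf("reaction '%s': delay must be >= 0 seconds", name))
  ord <- sum(reactants)
  if (rate_law == "michaelis_menten") {
    if (is.null(enzyme) || is.null(substrate) || is.null(Km))
      stop(sprintf("reaction '%s': michaelis_menten needs enzyme, substrate, Km",
                   name))
    if (!identical(sum(reactants), 1L) || names(reactants) != substrate)
      stop(sprintf("reaction '%s': the single reactant must be the substrate",
                   name))
    if (!is.numeric(Km) || Km <= 0)
      stop(sprintf("reaction '%s': Km must be positive (uM)", name))
    volume_class <- "michaelis-menten"
  } else {
    if (ord > 2L)
      stop(sprintf("reaction '%s': order %d > 2 is not supported", name, ord))
    if (is.null(volume_class))
      volume_class <- if (ord == 2L) "inverse-volume" else "volume-independent"
    volume_class <- match.arg(volume_class, .known_vclasses)
    if (volume_class == "inverse-volume" && ord != 2L)
      stop(sprintf("reaction '%s': inverse-volume class requires order 2, got order %d",
                   name, ord))
    if (volume_class == "proportional-volume" && ord != 0L)
      stop(sprintf("reaction '%s': proportional-volume class is only defined for order-0 influxes",
                   name))
    if (ord == 2L && volume_class != "inverse-volume")
      stop(sprintf("reaction '%s': order-2 channels must be inverse-volume",
                   name))
  }
  if (!is.null(rate_units)) {
    rate_units <- match.arg(rate_units, .known_units)
    if (rate_law == "mass_action" && ord == 2L &&
        !rate_units %in% c("per-uM-per-second", "uM-per-second"))
      stop(sprintf(
        "reaction '%s': order-2 channel needs per-uM-per-second units (got %s)",
        name, rate_units))
    # Printed tables sometimes give bimolecular constants as "uM/sec";
    # dimensional analysis requires per-uM-per-second and we read them so.
  }
  structure(list(name = name, reactants = reactants, products = products,
                 rate = rate, rate_units = rate_units,
                 volume_class = volume_class, delay = delay,
                 rate_law = rate_law, enzyme = enzyme, substrate = substrate,
                 Km = Km, noise = isTRUE(noise)),
            class = "reaction_def")
}

#' Total reactant stoichiometry of a reaction
#'
#' @param r a [reaction_def()].
#' @return Integer in `{0, 1, 2}` (1 for Michaelis-Menten channels, whose
#'   single reactant is the substrate).
#' @export
stoichiometric_order <- function(r) {
  stopifnot(inherits(r, "reaction_def"))
  as.integer(sum(r$reactants))
}

#' Define a transcription-factor binding site on a promoter
#'
#' @param tf species name of the transcription factor (e.g. a dimer).
#' @param kon binding rate in per-uM-per-second (bimolecular TF + free
#'   site; printed tables sometimes label this "uM/sec").
#' @param koff unbinding rate in 1/s.
#' @param factor multiplicative factor applied to the transcription rate
#'   while the site is occupied (e.g. 0.1 for a 10-fold repressor);
#'   factors for the unoccupied state are implicitly 1.
#' @return A `binding_site` list.
#' @export
binding_site <- function(tf, kon, koff, factor) {
  stopifnot(is.character(tf), length(tf) == 1L)
  if (!is.numeric(kon) || kon < 0 || !is.numeric(koff) || koff < 0)
    stop("binding/unbinding rates must be >= 0")
  if (!is.numeric(factor) || factor <= 0)
    stop("occupancy rate factor must be > 0")
  structure(list(tf = tf, kon = kon, koff = koff, factor = factor),
            class = "binding_site")
}

#' Define a chromosomal gene
#'
#' A gene is a replicating template: its copy number follows the
#' Cooper-Helmstetter schedule for its chromosomal position `p`, each live
#' copy (instance) carries an independently regulated promoter, and each
#' instance transcribes its mRNA species at rate
#' `a * prod(factor of occupied sites)`.
#'
#' @param name gene identifier.
#' @param position chromosomal position in `[0, 1]` (0 = origin,
#'   1 = terminus).
#' @param rate transcription rate `a` in per-gene-per-second.
#' @param mrna species name of the transcript.
#' @param sites list of [binding_site()]s (possibly empty).
#' @param delay transcription delay in seconds (0 = instantaneous release
#'   of the transcript).
#' @param initial_copies optional integer overriding the
#'   Cooper-Helmstetter copy number at birth (used e.g. to pin dosage in
#'   zero-growth validation runs).
#' @param cooperativity optional numeric vector of per-state multipliers on
#'   binding rates: element `k` multiplies `kon` when `k-1` other sites are
#'   already occupied on the same instance (default all 1).
#' @param noise logical; modulate `a` by the extrinsic-noise process.
#' @return A `gene_def` list.
#' @export
gene_def <- function(name, position, rate, mrna, sites = list(), delay = 0,
                     initial_copies = NULL, cooperativity = NULL,
                     noise = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  check_position(position)
  if (!is.numeric(rate) || rate <= 0)
    stop(sprintf("gene '%s': transcription rate must be > 0", name))
  if (!is.numeric(delay) || delay < 0)
    stop(sprintf("gene '%s': delay must be >= 0", name))
  sites <- lapply(sites, function(s) {
    if (inherits(s, "binding_site")) s
    else do.call(binding_site, s[c("tf", "kon", "koff", "factor")])
  })
  if (!is.null(initial_copies)) {
    if (initial_copies < 1 || initial_copies != round(initial_copies))
      stop(sprintf("gene '%s': initial_copies must be a positive integer", name))
    initial_copies <- as.integer(initial_copies)
  }
  if (!is.null(cooperativity)) {
    if (any(cooperativity <= 0))
      stop(sprintf("gene '%s': cooperativity multipliers must be > 0", name))
    if (length(cooperativity) < length(sites))
      cooperativity <- c(cooperativity,
                         rep(1, length(sites) - length(cooperativity)))
  }
  structure(list(name = name, position = position, rate = rate, mrna = mrna,
                 sites = sites, delay = delay,
                 initial_copies = initial_copies,
                 cooperativity = cooperativity, noise = isTRUE(noise)),
            class = "gene_def")
}

#' Assemble and validate a model
#'
#' Takes a structured description (lists of species, reactions and genes,
#' either as `*_def` objects or as plain lists of their fields) and returns
#' a validated `grow_model`. Validation covers: unique names, resolvable
#' species references, reaction order at most 2, positive rates,
#' volume-class/order consistency (inverse-volume only for bimolecular
#' channels) and Michaelis-Menten field completeness. Gene-derived channels
#' (per-instance transcription and site binding/unbinding) are not listed
#' statically: they are instantiated per gene copy by [new_cell_state()]
#' and grow when replication fires.
#'
#' @param definition a list with elements `species`, `reactions`, `genes`
#'   (each possibly empty/missing).
#' @return A `grow_model` object.
#' @export
build_model <- function(definition) {
  stopifnot(is.list(definition))
  mk <- function(x, ctor, cls) {
    if (is.null(x)) return(list())
    lapply(x, function(el) {
      if (inherits(el, cls)) el else do.call(ctor, el)
    })
  }
  species <- mk(definition$species, species_def, "species_def")
  reactions <- mk(definition$reactions, reaction_def, "reaction_def")
  genes <- mk(definition$genes, gene_def, "gene_def")

  sp_names <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(sp_names))
    stop("duplicate species names: ",
         paste(unique(sp_names[duplicated(sp_names)]), collapse = ", "))
  rx_names <- vapply(reactions, `[[`, "", "name")
  if (anyDuplicated(rx_names))
    stop("duplicate reaction names: ",
         paste(unique(rx_names[duplicated(rx_names)]), collapse = ", "))
  g_names <- vapply(genes, `[[`, "", "name")
  if (anyDuplicated(g_names))
    stop("duplicate gene names: ",
         paste(unique(g_names[duplicated(g_names)]), collapse = ", "))
  if (any(g_names %in% sp_names))
    stop("gene names must not collide with species names")

  ref_check <- function(nms, where) {
    bad <- setdiff(nms, sp_names)
    if (length(bad))
      stop(sprintf("%s references undeclared species: %s", where,
                   paste(bad, collapse = ", ")))
  }
  for (r in reactions) {
    ref_check(names(r$reactants), sprintf("reaction '%s'", r$name))
    ref_check(names(r$products), sprintf("reaction '%s'", r$name))
    if (r$rate_law == "michaelis_menten")
      ref_check(c(r$enzyme, r$substrate), sprintf("reaction '%s'", r$name))
  }
  for (g in genes) {
    ref_check(g$mrna, sprintf("gene '%s' (mRNA)", g$name))
    for (s in g$sites) ref_check(s$tf, sprintf("gene '%s' (TF)", g$name))
  }
  structure(list(species = species, reactions = reactions, genes = genes),
            class = "grow_model")
}

#' @export
print.grow_model <- function(x, ...) {
  cat(sprintf("grow_model: %d species, %d reactions, %d genes\n",
              length(x$species), length(x$reactions), length(x$genes)))
  if (length(x$species))
    cat("  species:", paste(vapply(x$species, `[[`, "", "name"),
                            collapse = ", "), "\n")
  for (r in x$reactions) {
    lhs <- if (length(r$reactants))
      paste(ifelse(r$reactants > 1, paste0(r$reactants, " "), ""),
            names(r$reactants), sep = "", collapse = " + ") else "0"
    rhs <- if (length(r$products))
      paste(ifelse(r$products > 1, paste0(r$products, " "), ""),
            names(r$products), sep = "", collapse = " + ") else "0"
    extra <- if (r$delay > 0) sprintf(" [delay %gs]", r$delay) else ""
    cat(sprintf("  %s: %s -> %s  (k = %g, %s)%s\n", r$name, lhs, rhs,
                r$rate, r$volume_class, extra))
  }
  for (g in x$genes)
    cat(sprintf("  gene %s: p = %g, a = %g -> %s, %d binding site(s)\n",
                g$name, g$position, g$rate, g$mrna, length(g$sites)))
  invisible(x)
}

species_names <- function(model) vapply(model$species, `[[`, "", "name")

# --- lowering to the numeric form consumed by the C++ engine ------------

# All indices 0-based. kappa pre-scaling is chosen so the engine only ever
# multiplies/divides by the current volume V (litres):
#   inverse-volume (order 2):   prop = kappa * X1 * X2 / V
#   volume-independent order 1: prop = kappa * X
#   volume-independent order 0: prop = kappa
#   proportional-volume:        prop = kappa * V
#   michaelis-menten:           prop = kappa * E * S / (KmNA * V + S)
compile_model <- function(model) {
  stopifnot(inherits(model, "grow_model"))
  sp <- species_names(model)
  idx <- function(nm) match(nm, sp) - 1L
  nr <- length(model$reactions)
  ord <- integer(nr); ri1 <- integer(nr); ri2 <- integer(nr)
  vclass <- integer(nr); kappa <- numeric(nr); delay <- numeric(nr)
  mm_e <- integer(nr); mm_s <- integer(nr); mm_KmNA <- numeric(nr)
  noise <- logical(nr)
  consume <- vector("list", nr); release <- vector("list", nr)
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    o <- sum(r$reactants)
    ord[j] <- o
    ri1[j] <- ri2[j] <- -1L
    if (o >= 1L) {
      expanded <- rep(names(r$reactants), r$reactants)
      ri1[j] <- idx(expanded[1])
      if (o == 2L) ri2[j] <- idx(expanded[2])
    }
    mm_e[j] <- -1L; mm_s[j] <- -1L; mm_KmNA[j] <- 0
    if (r$rate_law == "michaelis_menten") {
      vclass[j] <- 3L
      kappa[j] <- r$rate
      mm_e[j] <- idx(r$enzyme); mm_s[j] <- idx(r$substrate)
      mm_KmNA[j] <- r$Km * NA_PER_UM
    } else if (r$volume_class == "inverse-volume") {
      vclass[j] <- 1L
      kappa[j] <- r$rate / NA_PER_UM
    } else if (r$volume_class == "proportional-volume") {
      vclass[j] <- 2L
      kappa[j] <- r$rate * NA_PER_UM
    } else {
      vclass[j] <- 0L
      kappa[j] <- r$rate
    }
    delay[j] <- r$delay
    noise[j] <- r$noise
    # net stoichiometry: catalytic species (equal on both sides) untouched
    all_sp <- union(names(r$reactants), names(r$products))
    re <- sapply(all_sp, function(s) {
      v <- 0L
      if (s %in% names(r$reactants)) v <- v + r$reactants[[s]]
      v
    })
    pr <- sapply(all_sp, function(s) {
      v <- 0L
      if (s %in% names(r$products)) v <- v + r$products[[s]]
      v
    })
    net_c <- pmax(re - pr, 0L); net_r <- pmax(pr - re, 0L)
    ci <- which(net_c > 0L); pi <- which(net_r > 0L)
    consume[[j]] <- list(idx = idx(all_sp[ci]), n = as.integer(net_c[ci]))
    release[[j]] <- list(idx = idx(all_sp[pi]), n = as.integer(net_r[pi]))
  }
  ng <- length(model$genes)
  g_a <- numeric(ng); g_delay <- numeric(ng); g_mrna <- integer(ng)
  g_noise <- logical(ng); g_sites <- vector("list", ng)
  for (k in seq_len(ng)) {
    g <- model$genes[[k]]
    g_a[k] <- g$rate; g_delay[k] <- g$delay; g_mrna[k] <- idx(g$mrna)
    g_noise[k] <- g$noise
    ns <- length(g$sites)
    coop <- g$cooperativity
    if (is.null(coop)) coop <- rep(1, max(ns, 1L))
    g_sites[[k]] <- list(
      tf = if (ns) vapply(g$sites, function(s) idx(s$tf), 0L) else integer(0),
      kon = if (ns) vapply(g$sites, function(s) s$kon / NA_PER_UM, 0) else numeric(0),
      koff = if (ns) vapply(g$sites, `[[`, 0, "koff") else numeric(0),
      factor = if (ns) vapply(g$sites, `[[`, 0, "factor") else numeric(0),
      coop = as.numeric(coop))
  }
  list(nsp = length(sp), sp = sp,
       nr = nr, ord = ord, ri1 = ri1, ri2 = ri2, vclass = vclass,
       kappa = kappa, delay = delay, noise = noise,
       mm_e = mm_e, mm_s = mm_s, mm_KmNA = mm_KmNA,
       consume = consume, release = release,
       ng = ng, g_a = g_a, g_delay = g_delay, g_mrna = g_mrna,
       g_noise = g_noise, g_sites = g_sites,
       g_names = vapply(model$genes, `[[`, "", "name"))
}
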