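---
title: "Simulating gene circuits in growing, dividing bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating gene circuits in growing, dividing bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growSSA)
```

## The problem

The classic Gillespie stochastic simulation algorithm (SSA) assumes a
well-stirred reactor of fixed volume with a static set of channels. A
growing bacterium violates all three assumptions at once:

1. **Volume growth.** The cell volume increases exponentially,
   `V(t) = V_birth 2^((t - t_birth)/T)`, so every bimolecular propensity
   — which scales as `1/V` — decays continuously between reaction
   events, and concentration-defined influxes scale up with `V`.
2. **Gene dosage.** Chromosome replication doubles the copy number of
   each locus once per cycle, at a time set by the locus position; at
   fast growth (generation time `T` shorter than the replication `C` +
   division `D` periods) replication rounds overlap and a single gene
   exists in 2–8 copies.
3. **Delays.** Transcription and translation are multi-step polymer
   syntheses whose completion times are far from exponential; compressing
   them into single elementary steps misrepresents the dynamics. A fixed
   delay between initiation and product release is the standard remedy.
4. **Division.** Cells split; free molecules partition binomially between
   daughters while promoter occupancy states travel with their gene
   copies, which is how expression states are inherited epigenetically
   along a lineage.

`growSSA` implements an exact SSA extended with all four features, plus a
set of deliberately independent reference solvers (deterministic ODE,
delay-ODE, classic constant-volume SSA, dynamic flux-balance ODE) used as
oracles in the test suite.

## Units and the volume convention

All internal state is integer molecule counts. Concentrations are
micromolar, converted by `Omega(t) = N_A V(t) 1e-6` molecules per µM
(`omega_factor()`); rate constants carrying µM units are converted once
when a model is lowered for simulation. The default birth volume is
`1.1e-15` L — a typical *E. coli* — for which `Omega ≈ 662.4`, so a gene
dosage of 0.003 µM corresponds to about two copies per cell.

Propensities by volume-scaling class:

| class | order | propensity |
|---|---|---|
| volume-independent | 0 | `k` (molecules/s per cell) |
| proportional-volume | 0 | `k · Omega(t)` (`k` in µM/s; concentration-defined influx) |
| volume-independent | 1 | `k · X` |
| inverse-volume | 2 | `k · X₁X₂ / Omega(t)`, `k · X(X-1)/Omega(t)` for identical reactants |
| Michaelis–Menten | — | `kcat · E · S / (Km · Omega(t) + S)` |

Two notes on these choices. The count-based convention `X(X-1)` (rather
than `X²`) is used for identical-reactant channels on **both** sides of
every oracle comparison. Printed parameter tables in this literature
sometimes label bimolecular constants "µM/sec"; dimensional analysis of a
bimolecular step requires per-µM-per-second and the reader accepts the
printed label on order-2 channels under that interpretation (a
deliberate, documented reinterpretation rather than an assertion about
the original intent).

Zeroth-order channels default to volume-independent (a rate defined per
cell); proportional-volume is an explicit opt-in for influxes defined in
µM/s, whose molecular arrival rate must grow with the cell to keep
concentration dynamics consistent.

Michaelis–Menten channels are treated *quasi-statically*: the propensity
is evaluated at the current volume and held constant until the next
event. With event rates of order 10²–10³ s⁻¹ and µ = ln2/T ≈ 2×10⁻⁴ s⁻¹,
the within-interval volume drift is ~10⁻⁶ relative — far below Monte
Carlo noise.

## Exact firing times under exponential growth

Between events the total propensity is

`a(s) = A + b e^(-µs) + g e^(µs)`,

where `A` collects volume-independent channels, `b` the inverse-volume
channels evaluated now, `g` the proportional-volume influxes, and
`µ = ln 2 / T`. The cumulative hazard
(`survival_integral()`) is

`Λ(τ) = Aτ + (b/µ)(1 - e^(-µτ)) + (g/µ)(e^(µτ) - 1)`,

and the next firing time solves `Λ(τ) = -ln r` for a uniform draw `r`
(`sample_firing_time()`). Branches:

* `b = g = 0`: `τ = L/A` (the classic SSA).
* `A = g = 0`: the total hazard is bounded by `b/µ`, so with probability
  `e^(-b/µ)` **no reaction ever fires** (`NO_FIRING`, returned as `Inf`);
  otherwise `τ = -ln(1 - µL/b)/µ`.
* `A, b > 0, g = 0`: closed form through the principal branch of the
  Lambert W function,
  `τ = (L - b/µ)/A + W₀((b/A) e^(-µ(L - b/µ)/A))/µ`,
  evaluated in log space when the W argument would overflow, then
  polished with Newton steps on `Λ(τ) - L`.
* `g > 0`: `Λ` is unbounded and strictly increasing; safeguarded
  Newton/bisection.

Every branch honours the residual contract
`|Λ(τ) + ln r| ≤ 1e-10 (1 + |ln r|)`. The contract is not cosmetic: when
a delayed-reaction queue is dense, a sampler that is systematically
biased long will let scheduled events preempt *every* interval and
ordinary channels starve — the known precision trap of this algorithm
family. The test suite certifies the closed form against an independent
bisection oracle on a 1000-point parameter grid at 1e-9 relative
tolerance, and checks the sampled distribution against
`1 - e^(-Λ(τ))` by a Kolmogorov–Smirnov test.

## Gene dosage: deterministic Cooper–Helmstetter scheduling

Replication timing is deterministic and identical in all cells: the
C-period (fork travel, default 40 min) and D-period (termination to
division, default 20 min) are constants, and a locus at position
`p ∈ [0, 1]` is passed `C(1-p) + D` minutes before the division its round
licenses. Folding that lead time into the cycle gives

* doubling age `T - ((C(1-p) + D) mod T)` (`replication_age()`),
* copies at birth `2^floor((C(1-p)+D)/T)` (`copies_at_birth()`),
* population mean dosage `2^((C(1-p)+D)/T)` (`population_mean_dosage()`),
  which the tests verify against numerical quadrature of the step
  function under the exponential age density `(2 ln2/T) 2^(-a/T)`.

When the modulus is exactly zero the doubling coincides with division;
the convention here is that `replication_age()` returns `T`, the engine
executes the doubling immediately before division, and each daughter
inherits the pre-doubling per-daughter complement. A brute-force fork
simulator (initiations every `T`, forks at speed `1/C`) backs the closed
forms in the tests, including the 8-copy overlapping-cycle regime at
`T = 25` min.

At a replication event the engine doubles the gene's instances, each new
copy starting with an unoccupied, independently regulated promoter, and
any transcription factor bound to a replicated copy is released to the
free pool (the fork displaces it). New per-instance channels
(transcription, site binding/unbinding) join the channel set dynamically.

## Event loop, delays, division

The loop: compute the class-split propensities; sample `τ`; if a
scheduled event (delayed product release or gene replication) falls
inside the waiting interval, advance to it, execute it, and **resample**
— no reaction fires inside the interval. Ties at one timestamp run
delayed releases before replications. Delayed channels are *consuming*:
net reactants are removed at initiation and net products released
`τ_d` seconds later; species with equal stoichiometry on both sides
(catalytic templates, e.g. the mRNA in translation) are never touched.

At division (age exactly `T`) free molecules partition binomially
(`Binomial(n, 1/2)`; the complement goes to the other daughter, so
conservation is exact); species flagged non-partitionable are duplicated
to both daughters alongside their chromosome complement. Gene instances
split by sister-chromatid tag so each daughter receives an equal set of
copies with occupancy intact. Pending delayed releases are routed by an
independent fair coin — in this reaction semantics all delayed products
are free molecules, so no gene-associated routing arises. Both daughters
are simulated onward (a binary lineage tree, not a single mother line);
per-cell RNG substreams derive deterministically from `(seed, cell_id)`.

## Extrinsic noise

An optional Ornstein–Uhlenbeck process `η(t)` (shared across all flagged
rates and genes) multiplies selected rate constants as `k e^η` —
geometric, hence positive for any excursion. The exact conditional
transition is applied at every event over the elapsed inter-event time,
so the noise is piecewise-constant between events. With `σ = 0` the
engine is bitwise-identical to a noiseless run under the same seed
(no RNG draws are consumed). The source literature quotes no OU
parameter values; the suggested defaults (`τ_c = T/2`, `σ = 0.1`) are
placeholders, and cell-cycle-dependent parameter tables are out of scope.

## Reference solvers and reconstructed equations

The deterministic equations in the source text are partially unreadable
(figure placeholders), so the reference models are reconstructed from
the reaction lists and parameter tables; oracle status is claimed for
the reconstruction only.

**Negative autoregulation** (µM; `m` mRNA, `P` protein, `dm` free dimer,
`Gb` bound promoter, `Gf = G₀ - Gb`, `G₀ = 0.003` µM ≈ 2 copies):

```
dm/dt  = a (Gf + 0.1 Gb) - r₁ m
dP/dt  = b m - r₂ P - 2c P² + 2d dm
d(dm)/dt = c P² - d dm - K₁ dm Gf + K₂ Gb
dGb/dt = K₁ dm Gf - K₂ Gb
```

Promoter-bound dimer is booked separately from the free pool (the
original bookkeeping is not recoverable; this choice conserves dimer
exactly). The delayed variant replaces the translation term with
`b·m(t - τ)`. Integration is fixed-step RK4; the delay solver uses
cubic-Hermite history interpolation with at least 20 nodes per delay and
rejects steps larger than the delay. The system is stiff while
oscillating (the binding term `K₁·dm` reaches ~10² s⁻¹), hence the small
default step (`h = 0.01 s`) and a C++ inner loop.

**Classic SSA**: an independently written direct-method Gillespie at
constant volume (exponential waiting times, linear scan), used for the
zero-growth equivalence check. `flatten_gene_model()` rewrites
single-site genes as explicit `free`/`bound` promoter species, which is
exactly equivalent to per-instance bookkeeping at fixed copy number
because instances are exchangeable.

**Dynamic flux balance** (µM): metabolite M1 is taken up at a constant
concentration flux, enzyme a converts M1→M2 and enzyme b M2→M3 (both
`Kc E S/(Km + S)`), M1 and M3 are utilised at `r₃` (the parameter table
assigns `r₃` to M1 and M3 only), every species is diluted at
`µ = ln2/T` (printed as 0.0139 per minute for `T = 50`), and enzyme
synthesis follows each gene's Cooper–Helmstetter dosage step function —
that is how chromosome position enters the deterministic model.

## The packaged examples: what they state, and what a green test shows

* **`negautoreg`** — the printed autoregulation rates; `T = 200` min so
  growth is slow; gene at `p = 0.05` (near origin; the exact position is
  not printed) pinned to 2 copies at birth via the `initial_copies`
  override, because the printed comparison ("gene dosage approximately
  equal" to the 2-copy flat models) is otherwise unreachable — at
  `T = 200`, Cooper–Helmstetter arithmetic gives 1 copy at birth.
  The stochastic mean protein **count** sits above the fixed-volume ODE
  steady state: at equal concentration a growing cell holds up to
  `1/ln 2 ≈ 1.44×` more molecules on cycle average, and weakening
  dimerization at larger volume adds a genuine repression-relief effect.
  The packaged check asserts `ratio ∈ [1, 1.5]`: the lower bound is the
  qualitative claim, the upper bound is the volume-factor ceiling. (A
  tighter 1.25 cap would presume a concentration comparison; see the
  decisions record.)
* **`negautoreg_delay`** — the same circuit with a 1000 s translation
  delay over 400 min. Both the delay-ODE and the engine show sustained
  oscillations; the detector high-passes the series (running-mean window
  5000 s, removing cell-cycle dosage/volume trends) and requires an
  autocorrelation minimum below −0.3 after a 2000 s transient. Without
  the delay the score must stay above −0.3.
* **`toggle`** — two mutually repressing genes; the rates are the
  autoregulation table symmetrised (the source prints no toggle rates —
  these are explicitly non-printed stand-ins), `T = 50` min, both genes
  mid-chromosome. Colonies are run for five generations; cycle-averaged
  protein A vs protein B across the 16 complete cells of the last full
  generation is Pearson-anticorrelated in ≥95% of seeds. A green test
  establishes inherited bistable asymmetry, not any quantitative
  switching rate.
* **`flux_balanced` / `flux_unbalanced`** — the printed metabolic rates.
  The stochastic example runs at a reduced volume (1 µM ≡ 10 molecules):
  the source mixes molecule counts (metabolites start at 50 molecules)
  with µM rates (influx 100 µM/s), a regime that at the physical volume
  implies ~10⁵ events/s and is computationally out of reach; the reduced
  volume preserves the printed parameters and the position effect while
  keeping the run inside minutes. Balanced placement (both genes at
  `p = 0.5`) keeps input and output fluxes of M2 equal on cycle average;
  moving gene a to the origin (2 copies at birth, doubling at age
  40 min) and gene b to the terminus (1 copy, doubling at 30 min) raises
  the mean dosage ratio by ~50% and M2 accumulates to a far higher,
  far noisier level. The acceptance check is directional (unbalanced >
  balanced in mean and spread) in both the engine and the flux ODE; the
  two solvers intentionally run at different volumes and are not
  compared to each other numerically.

## Numerical choices and degenerate inputs

* Trajectories are recorded on a fixed output grid plus the endpoint; a
  grid point coinciding with an event records the **pre-event** state.
* Events scheduled exactly at the stopping time execute before the state
  is returned (so a replication at the division instant still leaves
  each daughter the correct complement).
* Daughters born exactly at the horizon are recorded as zero-length
  leaf cells.
* The ODE integrators clip negative excursions to zero and count them
  (`attr(x, "clipped")`); the packaged models never clip beyond roundoff.
* `lineage_correlation()` returns `NA` with a message for constant
  cycle-average series; it refuses fewer than 3 usable cells.
* The R reference stepper (`run_cell(method = "R")`) consumes the RNG
  stream draw-for-draw like the C++ engine and sums propensities
  sequentially in 64-bit doubles, so the two are bit-identical under a
  shared seed — the test suite asserts this.

## Known limitations

Replication initiation is noise-free and synchronous across chromosome
branches (no DnaA titration, no fork arrest); division is symmetric and
perfectly timed; promoters support general multi-site logic but the flat
classic-SSA flattening handles single-site promoters only; there is no
tau-leaping, no spatial structure, and no cell-to-cell communication.
The synthetic examples state parameter regimes, not biology: green tests
certify the algorithmic properties claimed above, not quantitative
agreement with any measured *E. coli* dataset.

## A worked session

```{r example}
md <- example_model("negautoreg")
md$model

per <- cycle_periods(T = 50, C = 40, D = 20)
c(origin = replication_age(0, per), terminus = replication_age(1, per))
population_mean_dosage(0, per)

res <- run_example("negautoreg", seed = 1, t_end = 6000)
str(res$summary)
```
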