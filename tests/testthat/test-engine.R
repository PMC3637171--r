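# Single-cell engine semantics: propensity split, channel selection,
# firing, replication, the event loop, and R/C++ agreement.

cfg_for <- function(model, T = 200, t_end = 1000, grid_dt = 10, ...) {
  run_config(T = T, t_end = t_end, grid_dt = grid_dt, ...)
}

test_that("compute_propensities: classes, dimerization, promoter factors", {
  m <- autoreg_model()
  cfg <- cfg_for(m)
  st <- new_cell_state(m, cfg)
  st$counts[] <- c(mRNA = 0L, protein = 100L, dimer = 0L)
  pr <- compute_propensities(st, m)
  # dimerization k=1/uM/s, V=1.1e-15 L: 100*99/662.4 ~ 14.95 /s
  dimer <- pr$channels$value[pr$channels$kind == "reaction" &
                              pr$channels$rxn == 4]
  expect_rel(dimer, 100 * 99 / omega_factor(1.1e-15), 1e-10)
  expect_rel(dimer, 14.95, 2e-3)
  expect_equal(pr$b, dimer)  # the only inverse-volume channel (no free dm)
  # protein decay in A, transcription a=1 per instance (2 instances)
  expect_rel(pr$A, 0.01 * 100 + 2 * 1, 1e-12)
  # per-channel values sum to A + b + g
  expect_rel(sum(pr$channels$value), pr$A + pr$b + pr$g, 1e-12)

  # repressor bound on one of two instances: transcription a*(1 + 0.1)
  st2 <- st
  st2$genes$gene_a$bound[1, 1] <- 1L
  pr2 <- compute_propensities(st2, m)
  tx <- pr2$channels$value[pr2$channels$kind == "transcription"]
  expect_equal(sum(tx), 1 * (1 + 0.1))

  # all counts zero, no zeroth-order channels -> A = b = g = 0 except
  # transcription (gene channels stay)
  m_flat <- build_model(list(
    species = list(species_def("x")),
    reactions = list(reaction_def("dec", c(x = 1), rate = 1))))
  st3 <- new_cell_state(m_flat, cfg_for(m_flat))
  pr3 <- compute_propensities(st3, m_flat)
  expect_equal(pr3$A + pr3$b + pr3$g, 0)

  st_bad <- st
  st_bad$counts[1] <- -1L
  expect_error(compute_propensities(st_bad, m), "internal-consistency")
})

test_that("select_channel matches propensity ratios", {
  m <- build_model(list(
    species = list(species_def("x", 3L), species_def("y", 1L)),
    reactions = list(reaction_def("r1", c(x = 1), rate = 1),     # prop 3
                     reaction_def("r2", c(y = 1), rate = 1))))   # prop 1
  cfg <- cfg_for(m)
  st <- new_cell_state(m, cfg)
  # two channels (3, 1): r2 = 0.9 -> cumulative 0.9*4 > 3 -> second
  ch <- select_channel(st, m, t_fire = st$t, r2 = 0.9)
  expect_equal(ch$rxn, 2L)
  expect_equal(select_channel(st, m, st$t, r2 = 0.5)$rxn, 1L)
  # Monte Carlo frequency over many draws (precompiled model: the ops
  # accept the lowered form directly)
  cm <- growSSA:::compile_model(m)
  set.seed(7)
  picks <- vapply(runif(5e3), function(r)
    select_channel(st, cm, st$t, r)$rxn, 0L)
  expect_lt(abs(mean(picks == 1L) - 0.75), 3 * sqrt(0.75 * 0.25 / 5e3))
})

test_that("fire_reaction: stoichiometry, delays, catalytic templates", {
  m <- autoreg_model(delay = 1000)
  cfg <- cfg_for(m)
  st <- new_cell_state(m, cfg)
  st$counts[] <- c(5L, 0L, 3L)
  ch <- compute_propensities(st, m)$channels
  # mRNA decay: 5 -> 4
  st2 <- fire_reaction(st, ch[ch$rxn == 2 & !is.na(ch$rxn), ], m)
  expect_equal(st2$counts[["mRNA"]], 4L)
  # delayed translation at t = 0: mRNA unchanged (catalytic template),
  # protein release enqueued at t + 1000
  st3 <- fire_reaction(st, ch[ch$rxn == 1 & !is.na(ch$rxn), ], m)
  expect_equal(st3$counts[["mRNA"]], 5L)
  expect_equal(st3$counts[["protein"]], 0L)
  expect_equal(st3$queue$time, 1000)
  # dimer binds a promoter instance: free dimer -1, occupancy set
  bindrow <- ch[ch$kind == "bind", ][1, ]
  st4 <- fire_reaction(st, bindrow, m)
  expect_equal(st4$counts[["dimer"]], 2L)
  expect_equal(st4$genes$gene_a$bound[bindrow$instance, 1], 1L)
  # unbind restores it
  ch4 <- compute_propensities(st4, m)$channels
  st5 <- fire_reaction(st4, ch4[ch4$kind == "unbind", ][1, ], m)
  expect_equal(st5$counts[["dimer"]], 3L)
  expect_equal(sum(st5$genes$gene_a$bound), 0L)
})

test_that("apply_replication doubles instances and frees bound TFs", {
  m <- autoreg_model(initial_copies = 1L)
  cfg <- cfg_for(m)
  st <- new_cell_state(m, cfg)
  st$counts[["dimer"]] <- 1L
  ch <- compute_propensities(st, m)$channels
  st <- fire_reaction(st, ch[ch$kind == "bind", ][1, ], m)
  expect_equal(st$counts[["dimer"]], 0L)
  # 1 instance with repressor bound -> 2 instances, both unbound, dimer +1
  st2 <- apply_replication(st, "gene_a", m)
  expect_equal(nrow(st2$genes$gene_a$bound), 2L)
  expect_equal(sum(st2$genes$gene_a$bound), 0L)
  expect_equal(st2$counts[["dimer"]], 1L)
  expect_equal(st2$genes$gene_a$tag, c(1L, 2L))
  # 2 unbound -> 4 unbound
  st3 <- apply_replication(st2, "gene_a", m)
  expect_equal(nrow(st3$genes$gene_a$bound), 4L)
  expect_equal(sum(st3$genes$gene_a$bound), 0L)
  # channel bookkeeping: +1 transcription and +1 site channel per new copy
  n2 <- nrow(compute_propensities(st2, m)$channels)
  n3 <- nrow(compute_propensities(st3, m)$channels)
  expect_equal(n3 - n2, 2L * 2L)
})

test_that("R reference stepper and C++ engine are draw-for-draw identical", {
  m <- autoreg_model(delay = 100)       # exercises the delayed queue too
  cfg <- run_config(T = 10, t_end = 10 * 60, grid_dt = 15)  # 1 division age
  st <- new_cell_state(m, cfg)
  set.seed(99); rc <- run_cell(st, m, cfg)
  set.seed(99); rr <- run_cell(st, m, cfg, method = "R")
  expect_identical(rc$trajectory, rr$trajectory)
  expect_identical(rc$state$counts, rr$state$counts)
  expect_identical(rc$state$queue$time, rr$state$queue$time)
  expect_identical(lapply(rc$state$genes, `[[`, "bound"),
                   lapply(rr$state$genes, `[[`, "bound"))
  expect_equal(rc$n_events, rr$n_events)
  expect_gt(rc$n_events, 50)            # the run actually did something
})

test_that("event loop: replication doubles copies at the scheduled age", {
  # no reactions at all: trajectory shows only the copy-number doubling
  m <- build_model(list(species = list(species_def("x")),
                        genes = list(gene_def("g", position = 0, rate = 1e-12,
                                              mrna = "x"))))
  cfg <- run_config(T = 50, t_end = 3000, grid_dt = 60)
  st <- new_cell_state(m, cfg)
  set.seed(1)
  res <- run_cell(st, m, cfg)
  tr <- res$trajectory
  # doubling at age 40 min = 2400 s (T=50, C=40, D=20, p=0); a grid point
  # coinciding with an event records the pre-event state
  expect_equal(unique(tr$copies_g[tr$time_s <= 2400]), 2L)
  expect_equal(unique(tr$copies_g[tr$time_s > 2400]), 4L)
})

test_that("pure birth-death at negligible growth reproduces the analytic mean", {
  m <- birth_death_model(a = 1, r1 = 2, copies = 2L)   # mean 2*a/r1 = 1
  cfg <- run_config(T = 1e6, t_end = 20000, grid_dt = 5)
  st <- new_cell_state(m, cfg)
  set.seed(5)
  res <- run_cell(st, m, cfg)
  x <- res$trajectory$mRNA[res$trajectory$time_s > 100]
  se <- stats::sd(x) / sqrt(length(x) / 3)  # ~3 grid points per lifetime
  expect_lt(abs(mean(x) - 1), 4 * se + 0.02)
  expect_true(all(res$trajectory$mRNA >= 0))
})

test_that("scheduled events preempt the sampled reaction", {
  # a delayed release at t=10 while the only channel is glacially slow:
  # the release executes first, then the loop resamples
  m <- build_model(list(
    species = list(species_def("x"), species_def("y")),
    reactions = list(
      reaction_def("make_y", c(x = 1), c(x = 1, y = 1), rate = 1e-9),
      reaction_def("delayed_src", c(x = 1), c(y = 1), rate = 1,
                   delay = 10))))
  cfg <- run_config(T = 1e5, t_end = 50, grid_dt = 1)
  st <- new_cell_state(m, cfg)
  st$queue <- data.frame(time = 10, kind = 0L, idx = 2L)  # pending release
  set.seed(3)
  res <- run_cell(st, m, cfg)
  tr <- res$trajectory
  expect_equal(tr$y[tr$time_s == 10], 0L)   # grid records pre-event state
  expect_equal(tr$y[tr$time_s == 11], 1L)
  expect_equal(nrow(res$state$queue), 0L)   # queue drained
})

test_that("delayed queue drains and counts stay nonnegative (property)", {
  m <- autoreg_model(delay = 150)
  cfg <- run_config(T = 40, t_end = 40 * 60 + 150, grid_dt = 20)
  for (s in 1:5) {
    set.seed(s)
    st <- new_cell_state(m, cfg)
    res <- run_cell(st, m, cfg, t_end = 40 * 60)     # one full cycle
    expect_true(all(as.matrix(res$trajectory[, 3:5]) >= 0))
    if (nrow(res$state$queue))
      expect_true(all(res$state$queue$time <= 40 * 60 + 150))
  }
})

test_that("volume law: doubling over one generation, mu = ln2/T", {
  m <- birth_death_model()
  cfg <- run_config(T = 60, t_end = 3600, grid_dt = 600)
  st <- new_cell_state(m, cfg)
  expect_equal(cell_volume(st, 3600) / cell_volume(st, 0), 2)
  set.seed(2)
  res <- run_cell(st, m, cfg)
  v <- res$trajectory$volume_L
  expect_rel(v[length(v)], 2 * v[1], 1e-12)
})
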