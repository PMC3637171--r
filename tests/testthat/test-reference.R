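# Reference solvers: autoreg ODE/DDE, classic SSA, flux model.

test_that("autoreg ODE: zero transcription stays at zero; steady state", {
  z <- integrate_autoreg_ode(autoreg_params(a = 1e-300), t_end = 200,
                             out_dt = 50)
  expect_true(all(abs(as.matrix(z[, -1])) < 1e-250))
  ss <- autoreg_steady_state()
  # Newton oracle on the reconstructed right-hand side (numeric Jacobian)
  rhs <- function(y) {
    p <- autoreg_params(); G0 <- 0.003
    m <- y[1]; P <- y[2]; dm <- y[3]; Gb <- y[4]; Gf <- G0 - Gb
    c(p[["a"]] * (Gf + p[["fac"]] * Gb) - p[["r1"]] * m,
      p[["b"]] * m - p[["r2"]] * P - 2 * p[["c"]] * P^2 +
        2 * p[["d"]] * dm,
      p[["c"]] * P^2 - p[["d"]] * dm - p[["K1"]] * dm * Gf +
        p[["K2"]] * Gb,
      p[["K1"]] * dm * Gf - p[["K2"]] * Gb)
  }
  y <- as.numeric(ss)
  for (it in 1:50) {   # Newton with numeric Jacobian
    f <- rhs(y)
    J <- matrix(0, 4, 4)
    for (j in 1:4) {
      dy <- y; h <- max(1e-9, 1e-7 * abs(y[j])); dy[j] <- dy[j] + h
      J[, j] <- (rhs(dy) - f) / h
    }
    y <- y - solve(J, f)
  }
  expect_true(all(abs(rhs(y)) < 1e-12))
  expect_equal(as.numeric(ss), y, tolerance = 1e-6)
  # long-time integration is converged: relative change < 1e-8 per 100 s
  tr <- integrate_autoreg_ode(t_end = attr(ss, "t_converged") + 200,
                              out_dt = 100)
  n <- nrow(tr)
  expect_lt(max(abs(tr[n, -1] - tr[n - 1, -1]) / pmax(tr[n, -1], 1e-12)),
            1e-7)
})

test_that("delay ODE: delay -> 0 converges to the plain ODE", {
  # the solution difference is O(delay): 0.1 s is inside the 1e-4 band
  plain <- integrate_autoreg_ode(t_end = 2000, out_dt = 20)
  near <- integrate_delayed_ode(delay = 0.1, t_end = 2000, out_dt = 20)
  expect_lt(max(abs(near$protein - plain$protein)), 1e-4)
  expect_identical(integrate_delayed_ode(delay = 0, t_end = 500,
                                         out_dt = 50)$protein,
                   integrate_autoreg_ode(t_end = 500, out_dt = 50)$protein)
  expect_error(integrate_delayed_ode(delay = 5, h = 10, t_end = 100),
               "larger than the delay")
})

test_that("delay ODE oscillates at delay 1000 s; plain ODE does not", {
  dde <- integrate_delayed_ode(delay = 1000, t_end = 24000)
  sc <- oscillation_score(dde$time_s, dde$protein)
  expect_lt(as.numeric(sc), -0.3)
  ode <- integrate_autoreg_ode(t_end = 24000)
  expect_gt(as.numeric(oscillation_score(ode$time_s, ode$protein)), -0.3)
})

test_that("classic SSA: Poisson stationary law and degenerate runs", {
  # birth-death: influx k molecules/s, decay r -> Poisson(k/r)
  m <- build_model(list(
    species = list(species_def("x", 0L)),
    reactions = list(
      reaction_def("in", products = c(x = 1), rate = 4,
                   rate_units = "molecules-per-second"),
      reaction_def("out", c(x = 1), rate = 0.5))))
  set.seed(71)
  res <- classic_ssa(m, t_end = 6000, grid_dt = 2)
  x <- res$trajectory$x[res$trajectory$time_s > 60]
  expect_lt(abs(mean(x) - 8), 0.35)          # mean k/r = 8
  expect_lt(abs(stats::var(x) / mean(x) - 1), 0.2)  # Fano ~ 1
  # zero production, zero molecules: nothing happens
  m0 <- build_model(list(
    species = list(species_def("x", 0L)),
    reactions = list(reaction_def("out", c(x = 1), rate = 1))))
  r0 <- classic_ssa(m0, t_end = 100, grid_dt = 10)
  expect_true(all(r0$trajectory$x == 0))
  expect_equal(r0$n_events, 0)
  # guards
  expect_error(classic_ssa(autoreg_model(), 10), "flat model")
  expect_error(classic_ssa(flatten_gene_model(autoreg_model(delay = 10)),
                           10), "delayed")
})

test_that("flatten_gene_model reproduces per-instance promoter kinetics", {
  flat <- flatten_gene_model(autoreg_model())
  expect_length(flat$genes, 0L)
  nms <- vapply(flat$species, `[[`, "", "name")
  expect_true(all(c("gene_a_free", "gene_a_bound") %in% nms))
  sp <- flat$species[[which(nms == "gene_a_free")]]
  expect_identical(sp$initial_count, 2L)
  expect_false(sp$partition_at_division)
  rx <- vapply(flat$reactions, `[[`, "", "name")
  expect_true(all(c("tx_gene_a", "tx_gene_a_repressed", "bind_gene_a",
                    "unbind_gene_a") %in% rx))
})

test_that("flux model: printed dilution rate, flux balance, accumulation", {
  # Table consistency: ln2 / 50 min rounds to the printed 0.0139 per min
  expect_equal(round(log(2) / 50, 4), 0.0139)
  p <- flux_params()
  expect_equal(unname(p["mu"]), log(2) / 3000)
  # symmetric positions: cycle-averaged input and output fluxes of M2
  # agree; M2 sits at a finite level
  bal <- integrate_flux_ode(positions = c(0.5, 0.5), t_end = 15000)
  win <- bal$time_s >= 12000
  vin <- mean(p[["Kc"]] * bal$enz_a[win] * bal$M1[win] /
                (p[["Km"]] + bal$M1[win]))
  vout <- mean(p[["Kc"]] * bal$enz_b[win] * bal$M2[win] /
                 (p[["Km"]] + bal$M2[win]))
  expect_lt(abs(vin - vout) / vin, 0.02)
  # gene b switched off (E_b -> 0): M2 accumulates monotonically towards
  # the dilution-limited balance
  noe <- integrate_flux_ode(positions = c(0.5, 0.5), t_end = 8000,
                            transcription = c(1, 0))
  late <- noe$time_s >= 2000   # after E_b has decayed away
  expect_true(all(diff(noe$M2[late]) > 0))
  expect_lt(max(noe$enz_b[late]), 0.05 * noe$enz_b[1])
  unb <- integrate_flux_ode(positions = c(0, 1), t_end = 15000)
  expect_gt(mean(unb$M2[unb$time_s >= 12000]), mean(bal$M2[win]))
  # dosage step functions carried in the output match the scheduler
  per <- cycle_periods(50)
  expect_equal(sort(unique(round(unb$dosage_a * omega_factor(1.1e-15)))),
               c(2, 4))
  expect_equal(sort(unique(round(unb$dosage_b * omega_factor(1.1e-15)))),
               c(1, 2))
})

test_that("oscillation_score guards and flat-series behaviour", {
  t <- seq(0, 20000, by = 10)
  flat <- rep(5, length(t))
  expect_equal(as.numeric(oscillation_score(t, flat)), 0)
  wave <- sin(2 * pi * t / 2500)
  expect_lt(as.numeric(oscillation_score(t, wave)), -0.8)
  expect_error(oscillation_score(t[-(1:3)], wave), "length")
})
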