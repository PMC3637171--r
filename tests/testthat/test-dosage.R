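test_that("replication ages and copy numbers match the printed schedule", {
  per <- cycle_periods(T = 50, C = 40, D = 20)
  # origin gene doubles 40 min after birth, terminus gene 30 min after
  expect_equal(replication_age(0, per), 40)
  expect_equal(replication_age(1, per), 30)
  expect_equal(replication_age(0.5, per), 10)
  expect_identical(copies_at_birth(0, per), 2L)
  expect_identical(copies_at_birth(1, per), 1L)
  expect_identical(copies_at_birth(0.3, cycle_periods(T = 200)), 1L)
  expect_identical(copies_at_birth(0, cycle_periods(T = 25)), 4L)
  expect_identical(copies_at_age(0, per, 39), 2L)
  expect_identical(copies_at_age(0, per, 41), 4L)
  expect_identical(copies_at_age(0, cycle_periods(T = 25), 20), 8L)
  expect_identical(copies_at_age(1, cycle_periods(T = 200), 0), 1L)
})

test_that("formula copy numbers equal the brute-force fork simulator", {
  grid <- expand.grid(p = c(0, 0.17, 0.5, 0.83, 1),
                      T = c(22, 25, 30, 50, 61, 120),
                      C = c(40, 33), D = c(20, 12))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    per <- cycle_periods(g$T, g$C, g$D)
    ages <- seq(0, g$T - 1e-9, length.out = 41)
    form <- copies_at_age(g$p, per, ages)
    oracle <- vapply(ages, function(a)
      fork_oracle_copies(g$p, g$T, g$C, g$D, a), 1)
    expect_equal(as.numeric(form), oracle,
                 info = sprintf("p=%g T=%g C=%g D=%g", g$p, g$T, g$C, g$D))
  }
})

test_that("copies_at_age is a right-continuous single doubling per cycle", {
  per <- cycle_periods(T = 35, C = 40, D = 20)
  ages <- seq(0, 35 - 1e-6, length.out = 500)
  cp <- copies_at_age(0.3, per, ages)
  expect_true(all(diff(cp) >= 0))
  expect_equal(sum(diff(cp) > 0), 1L)           # exactly one doubling
  expect_equal(max(cp), 2L * min(cp))
  ra <- replication_age(0.3, per)
  expect_identical(copies_at_age(0.3, per, ra), 2L * copies_at_birth(0.3, per))
  # max instantaneous copies over a cycle: 2^(floor(lead/T)+1); the
  # printed overlap extreme is 8 simultaneous copies for an origin gene
  expect_identical(max(copies_at_age(0, cycle_periods(T = 25),
                                     seq(0, 24.99, by = 0.01))), 8L)
})

test_that("boundary convention: doubling exactly at division", {
  # lead C(1-p)+D = 50 = T: modulus zero
  per <- cycle_periods(T = 50, C = 40, D = 10)
  expect_equal(replication_age(0, per), 50)      # returns T, not 0
  expect_identical(copies_at_birth(0, per), 2L)
  expect_identical(copies_at_age(0, per, 49.999), 2L)  # constant in-cycle
})

test_that("population mean dosage equals the age-density expectation", {
  for (p in c(0, 0.25, 0.5, 1)) for (T in c(25, 50, 200)) {
    per <- cycle_periods(T)
    f <- function(a) copies_at_age(p, per, a) * (2 * log(2) / T) * 2^(-a / T)
    num <- stats::integrate(Vectorize(f), 0, T, rel.tol = 1e-12,
                            subdivisions = 2000L)$value
    expect_rel(population_mean_dosage(p, per), num, 1e-9)
  }
  expect_rel(population_mean_dosage(0, cycle_periods(50)), 2^1.2, 1e-12)
  expect_rel(population_mean_dosage(0.5, cycle_periods(50)), 2^0.8, 1e-12)
  # no replication in progress in the slow-growth limit
  expect_lt(population_mean_dosage(1, cycle_periods(1e6)) - 1, 1e-4)
})

test_that("replication_schedule composes ages and sorts with stable ties", {
  per <- cycle_periods(T = 50)
  g0 <- gene_def("a", 0, 1, "x"); g1 <- gene_def("b", 1, 1, "x")
  sch <- replication_schedule(list(g0, g1), per, t_birth = 0, t_end = 50)
  expect_equal(sch$time, c(30, 40))
  expect_equal(sch$gene, c("b", "a"))
  expect_equal(sch$event, rep("replication", 2))
  # several cycles: events at age + k*T
  sch3 <- replication_schedule(list(g0), per, 0, 150)
  expect_equal(sch3$time, c(40, 90, 140))
  # empty gene list -> empty schedule
  expect_identical(nrow(replication_schedule(list(), per, 0, 100)), 0L)
  # ties broken by declaration order
  sch_tie <- replication_schedule(list(g0, gene_def("a2", 0, 1, "x")), per,
                                  0, 50)
  expect_equal(sch_tie$gene, c("a", "a2"))
  expect_error(replication_schedule(list(g0), per, 10, 10), "t_end")
})

test_that("invalid inputs are rejected", {
  per <- cycle_periods(50)
  expect_error(replication_age(-0.1, per), "within")
  expect_error(replication_age(NaN, per), "finite")
  expect_error(copies_at_age(0, per, 50), "\\[0, T\\)")
  expect_error(cycle_periods(0), "> 0")
})
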