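# Firing-time machinery: cumulative hazard, Lambert-W closed form,
# branch behaviour. The full 1000-point certification grid lives in
# test-acceptance.R.

test_that("survival_integral matches adaptive quadrature of the hazard", {
  cases <- expand.grid(A = c(0, 1, 10), b = c(0, 2, 50), g = c(0, 0.5),
                       mu = c(1e-4, 0.01, 0.3), tau = c(0.1, 3, 10))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    num <- stats::integrate(function(s)
      cs$A + cs$b * exp(-cs$mu * s) + cs$g * exp(cs$mu * s),
      0, cs$tau, rel.tol = 1e-12)$value
    expect_rel(survival_integral(cs$A, cs$b, cs$g, cs$mu, cs$tau), num,
               1e-9)
  }
  # closed-form spot values
  expect_equal(survival_integral(1, 0, 0, 0.5, 3), 3)          # constant
  expect_equal(survival_integral(0, 1, 0, 1e-12, 3), 3, tolerance = 1e-6)
  expect_rel(survival_integral(1, 2, 0, 0.01, 10),
             10 + 200 * (1 - exp(-0.1)), 1e-12)                # 29.0325
})

test_that("sample_firing_time branches behave as specified", {
  # classic SSA limit
  expect_equal(sample_firing_time(A = 1, b = 0, mu = 0.01, r = exp(-1)), 1)
  # pure inverse-volume: bounded hazard
  expect_rel(sample_firing_time(A = 0, b = 1, mu = 0.01, r = exp(-0.5)),
             -100 * log(0.995), 1e-10)
  expect_identical(sample_firing_time(A = 0, b = 1, mu = 1, r = exp(-2)),
                   Inf)                                        # mu*L/b = 2
  expect_identical(sample_firing_time(A = 0, b = 0, g = 0, mu = 0.01,
                                      r = 0.5), Inf)           # no channels
  # residual contract on the Lambert path
  tau <- sample_firing_time(A = 1, b = 1, mu = log(2) / 12000, r = 0.5)
  L <- -log(0.5)
  expect_lt(abs(survival_integral(1, 1, 0, log(2) / 12000, tau) - L),
            1e-10 * (1 + L))
  # g > 0 root-finding branch
  tau_g <- sample_firing_time(A = 0.5, b = 1, g = 2, mu = 0.02, r = 0.3)
  Lg <- -log(0.3)
  expect_lt(abs(survival_integral(0.5, 1, 2, 0.02, tau_g) - Lg),
            1e-10 * (1 + Lg))
  # validation
  expect_error(sample_firing_time(1, 0, 0, 0.01, 0), "r must lie")
  expect_error(sample_firing_time(-1, 0, 0, 0.01, 0.5), "negative")
})

test_that("Lambert W solves w exp(w) = x across its domain", {
  for (x in c(-exp(-1) + 1e-12, -0.2, 0, 1e-8, 0.5, 1, 10, 500, 1e8)) {
    w <- lambert_w0(x)
    expect_lt(abs(w * exp(w) - x), 1e-10 * (1 + abs(x)))
  }
  expect_equal(lambert_w0(exp(1)), 1, tolerance = 1e-12)
})

test_that("sampled waiting times follow 1 - exp(-Lambda) (PIT uniformity)", {
  set.seed(101)
  A <- 0.7; b <- 1.8; g <- 0; mu <- log(2) / 3000
  r <- runif(1e4)
  tau <- vapply(r, function(ri) sample_firing_time(A, b, g, mu, ri), 0)
  u <- exp(-vapply(tau, function(tt) survival_integral(A, b, g, mu, tt), 0))
  ks <- suppressWarnings(stats::ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and with a growing-influx component
  r2 <- runif(5e3)
  tau2 <- vapply(r2, function(ri)
    sample_firing_time(0.2, 0.5, 1.5, 0.005, ri), 0)
  u2 <- exp(-vapply(tau2, function(tt)
    survival_integral(0.2, 0.5, 1.5, 0.005, tt), 0))
  expect_gt(suppressWarnings(stats::ks.test(u2, "punif"))$p.value, 0.01)
})
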