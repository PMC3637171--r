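test_that("build_model assembles and validates the autoregulation system", {
  m <- autoreg_model()
  expect_s3_class(m, "grow_model")
  expect_length(m$species, 3L)   # mRNA, protein, dimer; promoter is a gene
  expect_length(m$genes, 1L)
  # printed rates carried verbatim
  rx <- stats::setNames(m$reactions,
                        vapply(m$reactions, `[[`, "", "name"))
  expect_equal(rx$translation$rate, 1)
  expect_equal(rx$mrna_degradation$rate, 2)
  expect_equal(rx$protein_decay$rate, 0.01)
  expect_equal(rx$dimerization$rate, 1)
  expect_equal(rx$dimer_dissociation$rate, 1)
  g <- m$genes[[1]]
  expect_equal(g$rate, 1)
  expect_equal(g$sites[[1]]$kon, 100)
  expect_equal(g$sites[[1]]$koff, 0.1)
  expect_equal(g$sites[[1]]$factor, 0.1)
})

test_that("degenerate and invalid definitions", {
  # empty reaction list, one species -> valid model with no dynamics
  m0 <- build_model(list(species = list(species_def("x", 5L))))
  expect_s3_class(m0, "grow_model")
  expect_length(m0$reactions, 0L)
  # undeclared species reference names the reaction
  expect_error(build_model(list(
    species = list(species_def("x")),
    reactions = list(reaction_def("leak", c(ghost = 1), rate = 1)))),
    "leak.*ghost")
  # order > 2
  expect_error(reaction_def("tri", c(x = 3), rate = 1), "order 3")
  # inverse-volume on a first-order channel names the reaction
  expect_error(reaction_def("bad", c(x = 1), rate = 1,
                            volume_class = "inverse-volume"),
               "bad.*inverse-volume")
  # order-2 channels must be inverse-volume with bimolecular units
  expect_error(reaction_def("dim", c(x = 2), rate = 1,
                            volume_class = "volume-independent"),
               "inverse-volume")
  expect_error(reaction_def("dim", c(x = 2), rate = 1,
                            rate_units = "per-second"), "per-uM-per-second")
  expect_error(reaction_def("neg", c(x = 1), rate = -2), "positive")
  expect_error(reaction_def("dly", c(x = 1), rate = 1, delay = -1), ">= 0")
  expect_error(build_model(list(species = list(species_def("x"),
                                               species_def("x")))),
               "duplicate")
  # michaelis-menten needs its fields
  expect_error(reaction_def("mm", c(x = 1), rate = 1,
                            rate_law = "michaelis_menten"),
               "enzyme, substrate, Km")
})

test_that("stoichiometric_order sums reactant stoichiometries", {
  expect_identical(stoichiometric_order(
    reaction_def("dim", c(p = 2), c(d = 1), rate = 1)), 2L)
  expect_identical(stoichiometric_order(
    reaction_def("dec", c(m = 1), rate = 1)), 1L)
  expect_identical(stoichiometric_order(
    reaction_def("in", products = c(m = 1), rate = 1)), 0L)
})

test_that("unit lowering: kappa scalings reproduce dimensional analysis", {
  m <- autoreg_model()
  cm <- growSSA:::compile_model(m)
  # order-2: propensity k*X*(X-1)/Omega with Omega = N_A*V*1e-6
  V <- 1.1e-15
  j <- which(vapply(m$reactions, `[[`, "", "name") == "dimerization")
  expect_rel(cm$kappa[j] * 100 * 99 / V, 100 * 99 / omega_factor(V), 1e-12)
  expect_rel(omega_factor(1.1e-15), 662.4, 2e-4)  # ~662.4 molecules per uM
})

test_that("gene dosage 0.003 uM is about two copies at the default volume", {
  # the deterministic model's promoter concentration back-converted
  expect_equal(round(0.003 * omega_factor(1.1e-15)), 2)
})
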