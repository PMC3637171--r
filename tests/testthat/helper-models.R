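# Small models and oracles shared across the test files.

# pure birth-death mRNA: transcription from `copies` gene copies at rate a,
# first-order decay r1
birth_death_model <- function(a = 1, r1 = 2, copies = 2L) {
  build_model(list(
    species = list(species_def("mRNA", 0L)),
    genes = list(gene_def("g", position = 0, rate = a, mrna = "mRNA",
                          initial_copies = copies)),
    reactions = list(reaction_def("decay", reactants = c(mRNA = 1),
                                  rate = r1))))
}

# the autoregulation circuit built in code (same rates as the packaged
# negautoreg file)
autoreg_model <- function(delay = 0, initial_copies = 2L,
                          position = 0.05) {
  build_model(list(
    species = list(species_def("mRNA"), species_def("protein"),
                   species_def("dimer")),
    reactions = list(
      reaction_def("translation", c(mRNA = 1),
                   c(mRNA = 1, protein = 1), rate = 1, delay = delay),
      reaction_def("mrna_degradation", c(mRNA = 1), rate = 2),
      reaction_def("protein_decay", c(protein = 1), rate = 0.01),
      reaction_def("dimerization", c(protein = 2), c(dimer = 1), rate = 1),
      reaction_def("dimer_dissociation", c(dimer = 1), c(protein = 2),
                   rate = 1)),
    genes = list(gene_def("gene_a", position = position, rate = 1,
                          mrna = "mRNA", initial_copies = initial_copies,
                          sites = list(binding_site("dimer", kon = 100,
                                                    koff = 0.1,
                                                    factor = 0.1))))))
}

# brute-force Cooper-Helmstetter fork simulator: initiation every T
# minutes at the ages where a fork must start so that its round finishes
# C + D before a (possibly later) division; forks advance at speed 1/C.
# Returns the copy number of a locus at position p at cell age `age`.
fork_oracle_copies <- function(p, T, C, D, age) {
  # the round licensing the division at absolute time k*T initiates at
  # k*T - (C + D) (possibly in an ancestor) and its fork passes locus p at
  # k*T - (C*(1-p) + D). For a cell born at 0 observed at age `age`, the
  # copy number is 2^(number of rounds already past p whose division has
  # not yet happened): doubling on fork passage, halving at division.
  lead <- C * (1 - p) + D
  kmax <- ceiling(lead / T) + 2
  active <- sum(vapply(1:kmax, function(k)
    (k * T - lead) <= age && age < k * T, TRUE))
  2^active
}

expect_rel <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}
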