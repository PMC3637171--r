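# Division, partitioning, inheritance, lineage trees.

test_that("partition_binomial conserves molecules and is unbiased", {
  set.seed(11)
  # exact conservation over many random count vectors
  for (i in 1:200) {
    n <- sample(0:500, 4)
    pp <- partition_binomial(stats::setNames(n, letters[1:4]))
    expect_identical(pp$d1 + pp$d2, stats::setNames(as.integer(n),
                                                    letters[1:4]))
    expect_true(all(pp$d1 >= 0) && all(pp$d2 >= 0))
  }
  expect_identical(unname(partition_binomial(c(x = 0L))$d1), 0L)
  # mean of d1 at n=100 over many draws: binomial(100, 1/2)
  d1 <- vapply(1:2e4, function(i) partition_binomial(c(x = 100L))$d1, 0L)
  expect_lt(abs(mean(d1) - 50), 4 * 5 / sqrt(2e4))
  # non-partitioned species go whole to both daughters
  q <- partition_binomial(c(x = 7L), partition = FALSE)
  expect_identical(unname(q$d1), 7L)
  expect_identical(unname(q$d2), 7L)
})

test_that("divide splits chromosomes evenly and inherits occupancy", {
  m <- autoreg_model(initial_copies = 2L)
  cfg <- run_config(T = 50, t_end = 3000, grid_dt = 50)
  st <- new_cell_state(m, cfg)
  st <- apply_replication(st, "gene_a", m)   # 4 copies, tags 1,1,2,2
  st$counts[["dimer"]] <- 1L
  ch <- compute_propensities(st, m)$channels
  st <- fire_reaction(st, ch[ch$kind == "bind", ][1, ], m)  # repress copy 1
  st$t <- st$t_birth + st$T_s
  set.seed(21)
  dd <- divide(st, m)
  # 4 copies -> each daughter gets 2
  expect_equal(nrow(dd$d1$genes$gene_a$bound), 2L)
  expect_equal(nrow(dd$d2$genes$gene_a$bound), 2L)
  # exactly one daughter inherits the repressed instance, state intact
  expect_equal(sum(dd$d1$genes$gene_a$bound) +
                 sum(dd$d2$genes$gene_a$bound), 1L)
  # daughters are newborn at the mother's division time
  expect_equal(dd$d1$t_birth, st$t)
  expect_equal(cell_volume(dd$d1), cfg$V_birth)
  # conservation of every species
  expect_identical(dd$d1$counts + dd$d2$counts, st$counts)
  # not at division age -> error; odd complement -> error
  expect_error(divide(dd$d1, m), "division age")
  st_odd <- st
  st_odd$genes$gene_a$tag <- c(1L, 1L, 1L, 2L)
  expect_error(divide(st_odd, m), "unsplittable")
})

test_that("colony trees have the right shape and timing", {
  m <- birth_death_model()
  cfg <- run_config(T = 10, t_end = 3 * 600, grid_dt = 60, seed = 8)
  tree <- simulate_colony(m, cfg)
  nd <- tree$nodes
  # divisions at exactly t_end spawn newborn leaves: full binary tree,
  # 8 leaves after 3 generation times
  expect_equal(nrow(nd), 15L)
  leaves <- setdiff(nd$cell_id, nd$parent_id)
  expect_length(leaves, 8L)
  # child birth time equals parent division time
  for (i in which(nd$parent_id > 0)) {
    expect_equal(nd$birth_s[i],
                 nd$division_s[nd$cell_id == nd$parent_id[i]])
  }
  expect_false(tree$truncated)
  # max_cells truncation warns and flags
  cfg2 <- run_config(T = 10, t_end = 3 * 600, grid_dt = 60, seed = 8,
                     max_cells = 4L)
  expect_warning(tree2 <- simulate_colony(m, cfg2), "max_cells")
  expect_true(tree2$truncated)
  expect_lte(nrow(tree2$nodes), 4L + 2L)
  # determinism: same seed, same tree and trajectories
  tree3 <- simulate_colony(m, cfg)
  expect_identical(tree$nodes, tree3$nodes)
  expect_identical(tree$trajectories, tree3$trajectories)
})

test_that("epigenetic inheritance: frozen promoter states persist", {
  # with binding and unbinding frozen (rates ~0), promoter occupancy is
  # altered by nothing but fork passage; in particular the division
  # operator hands each state to exactly one daughter, unchanged. The
  # engine segment runs up to just before the replication age so the
  # occupancy must come through the whole cycle intact.
  m <- build_model(list(
    species = list(species_def("mRNA"), species_def("rep", 10L)),
    reactions = list(reaction_def("dec", c(mRNA = 1), rate = 1)),
    genes = list(gene_def("g", 0, 1, "mRNA", initial_copies = 2L,
                          sites = list(binding_site("rep", kon = 1e-30,
                                                    koff = 1e-30,
                                                    factor = 0.1))))))
  cfg <- run_config(T = 50, t_end = 2399, grid_dt = 60, seed = 13)
  init <- new_cell_state(m, cfg)
  init$genes$g$bound[1, 1] <- 1L   # one of two instances repressed
  init$counts[["rep"]] <- 9L
  set.seed(13)
  r1 <- run_cell(init, m, cfg)     # stops just before fork passage
  expect_equal(sum(r1$state$genes$g$bound), 1L)
  # arbitrary chain of divisions on a 2-instance carrier state
  carrier <- r1$state
  set.seed(77)
  for (gen in 1:6) {
    carrier$t <- carrier$t_birth + carrier$T_s   # at division age
    dd <- divide(carrier, m)
    expect_equal(sum(dd$d1$genes$g$bound) + sum(dd$d2$genes$g$bound), 1L)
    expect_equal(nrow(dd$d1$genes$g$bound), 1L)
    expect_equal(nrow(dd$d2$genes$g$bound), 1L)
    carrier <- if (sum(dd$d1$genes$g$bound)) dd$d1 else dd$d2
    # regrow the complement as two instances for the next division,
    # keeping the occupied state (frozen rates: nothing may change it)
    carrier$genes$g$bound <- rbind(carrier$genes$g$bound, 0L)
    carrier$genes$g$tag <- c(1L, 2L)
  }
  expect_equal(sum(carrier$genes$g$bound), 1L)
})

test_that("lineage_correlation: identity, independence, guards", {
  m <- build_model(list(
    species = list(species_def("x"), species_def("y")),
    genes = list(gene_def("gx", 0.5, 2, "x", initial_copies = 1L),
                 gene_def("gy", 0.5, 2, "y", initial_copies = 1L)),
    reactions = list(reaction_def("dx", c(x = 1), rate = 0.02),
                     reaction_def("dy", c(y = 1), rate = 0.02))))
  cfg <- run_config(T = 20, t_end = 4 * 1200 - 1, grid_dt = 30, seed = 4)
  tree <- simulate_colony(m, cfg)
  # a species against itself
  expect_equal(lineage_correlation(tree, "x", "x"), 1)
  # independent constitutive genes across many cells: |r| small
  r <- lineage_correlation(tree, "x", "y", cells = "complete")
  expect_lt(abs(r), 0.75)   # wide null bound, few cells
  expect_error(lineage_correlation(tree, "x", "y", cells = c(1L, 2L)),
               "at least 3")
  # constant series -> NA with a message
  tree0 <- tree
  for (nm in names(tree0$trajectories)) tree0$trajectories[[nm]]$x <- 5L
  expect_message(r0 <- lineage_correlation(tree0, "x", "y"), "constant")
  expect_true(is.na(r0))
})

test_that("newick export parses and mirrors the tree", {
  m <- birth_death_model()
  cfg <- run_config(T = 10, t_end = 1500, grid_dt = 60, seed = 2)
  tree <- simulate_colony(m, cfg)   # 2.5 generations: 7 cells, 4 leaves
  expect_equal(nrow(tree$nodes), 7L)
  nwk <- lineage_newick(tree)
  ph <- ape::read.tree(text = nwk)
  expect_equal(ape::Ntip(ph), 4L)
  expect_setequal(ph$tip.label, paste0("c", 4:7))
  # branch lengths are lifetimes (leaves truncated at t_end)
  expect_equal(sort(unique(ph$edge.length)), c(300, 600))
  # annotated form still contains every cell id
  ann <- lineage_newick(tree, annotate = TRUE)
  expect_true(all(vapply(1:7, function(i)
    grepl(sprintf("cell_id=%d,", i), ann), TRUE)))
})

test_that("long-format table covers every cell, time and species", {
  m <- birth_death_model()
  cfg <- run_config(T = 10, t_end = 900, grid_dt = 100, seed = 2)
  tree <- simulate_colony(m, cfg)
  lf <- as.data.frame(tree)
  expect_named(lf, c("cell_id", "time_s", "species", "value"))
  expect_setequal(unique(lf$species), c("mRNA", "copies_g"))
  expect_setequal(unique(lf$cell_id), tree$nodes$cell_id)
})
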