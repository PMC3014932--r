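# Synthetic-data generator: tree simulation, sequence evolution, and the
# whole-genome-style fixture.

test_that("simulated chronograms are ultrametric with the requested tip count;
           fixed trees pass through", {
  spec <- simulation_spec(10, birth = 1, death = 0.2, partitions = list(
    p = list(length = 10L, rate = 1, model = gtr_model())), sigma = 0, seed = 5)
  ch <- simulate_chronogram(spec)
  expect_equal(length(ch$tree$tip.label), 10)
  d <- ape::node.depth.edgelength(ch$tree)
  expect_lt(diff(range(d[1:10])), 1e-6)
  # fixed newick source returns the same dated tree
  spec2 <- simulation_spec(3, tree = "((a:1,b:1):1,c:2);", partitions = list(
    p = list(length = 10L, rate = 1, model = gtr_model())), sigma = 0, seed = 5)
  ch2 <- simulate_chronogram(spec2)
  expect_equal(max(ch2$ages), 2)
  expect_setequal(ch2$tree$tip.label, c("a", "b", "c"))
  expect_error(simulation_spec(4, partitions = list(
    p = list(length = 10L, rate = 1, model = gtr_model()))), "seed")
})

test_that("doubling the pure-birth rate halves the mean root age", {
  ages <- sapply(c(1, 2), function(b) {
    mean(sapply(1:250, function(i) {
      spec <- simulation_spec(8, birth = b, death = 0, partitions = list(
        p = list(length = 10L, rate = 1, model = gtr_model())), sigma = 0,
        seed = 1000 * b + i)
      max(simulate_chronogram(spec)$ages)
    }))
  })
  expect_equal(ages[1] / ages[2], 2, tolerance = 0.15)
})

test_that("zero rate leaves a partition constant across taxa", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  spec <- simulation_spec(3, tree = chronogram(tr), partitions = list(
    frozen = list(length = 200L, rate = 1e-12, model = gtr_model()),
    live = list(length = 200L, rate = 0.5, model = gtr_model())),
    sigma = 0, seed = 8)
  aln <- simulate_alignment(chronogram(tr), spec)
  frozen <- aln$matrix[, aln$labels == "frozen"]
  expect_true(all(frozen[1, ] == frozen[2, ] & frozen[1, ] == frozen[3, ]))
  live <- aln$matrix[, aln$labels == "live"]
  expect_gt(mean(live[1, ] != live[3, ]), 0.05)
})

test_that("two-taxon identity fraction matches the JC closed form", {
  # divergence d on each side: P(identical) = 1/4 + 3/4 exp(-8d/3... using
  # total path 2d: 1/4 + 3/4 exp(-4 (2d) / 3)
  d <- 0.15
  tr <- ape::read.tree(text = sprintf("(a:%g,b:%g);", d, d))
  spec <- simulation_spec(2, tree = chronogram(tr), partitions = list(
    p = list(length = 50000L, rate = 1, model = gtr_model())), sigma = 0,
    seed = 13)
  aln <- simulate_alignment(chronogram(tr), spec)
  obs <- mean(aln$matrix[1, ] == aln$matrix[2, ])
  expected <- 1 / 4 + 3 / 4 * exp(-4 * (2 * d) / 3)
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / 50000) + 1e-4)
})

test_that("long simulations converge to the stationary base composition", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  m <- gtr_model(c(2, 8, 1, 1.5, 10, 1), c(0.4, 0.3, 0.1, 0.2), 0, 1)
  spec <- simulation_spec(4, tree = chronogram(tr), partitions = list(
    p = list(length = 30000L, rate = 0.8, model = m)), sigma = 0, seed = 17)
  aln <- simulate_alignment(chronogram(tr), spec)
  obs <- empirical_frequencies(aln)
  chi <- 30000 * 4 * sum((obs - m$freqs)^2 / m$freqs)
  expect_lt(max(abs(obs - m$freqs)), 0.01)
})

test_that("the whole-genome fixture has the advertised structure and a
           saturating control-region stand-in", {
  fx <- make_wg_fixture(seed = 4)
  expect_equal(length(fx$alignment$taxa), 16)
  expect_equal(ncol(fx$alignment$matrix), 15049)
  expect_equal(length(fx$wg_columns), 14471)
  expect_equal(sum(lengths(fx$scheme$partitions)), 15049)
  expect_named(fx$candidates, paste0("t", 1:18))
  # deterministic per seed
  fx2 <- make_wg_fixture(seed = 4)
  expect_identical(fx$alignment$matrix, fx2$alignment$matrix)
  # region widths mirror the three-gene extraction
  ext <- extract_regions(fx$alignment, fx$regions)
  expect_equal(ncol(ext$matrix), 1952)
  # hypervariable partition saturates between deep taxa while codon1 does not
  X <- fx$alignment$matrix
  dl <- which(fx$alignment$labels == "dloop")
  c1 <- which(fx$alignment$labels == "codon1")
  deep_dl <- mean(X["Vole", dl] != X["Mouse", dl])
  deep_c1 <- mean(X["Vole", c1] != X["Mouse", c1])
  shallow_dl <- mean(X["Rsor", dl] != X["Rvil", dl])
  expect_gt(deep_dl, 0.55)   # near the multiple-hit ceiling
  expect_lt(deep_c1, 0.35)
  expect_lt(shallow_dl, 0.30) # still informative at shallow depths
  # truth record supports recovery tests without re-simulation
  expect_named(fx$truth$models, names(fx$scheme$partitions), ignore.order = TRUE)
  expect_equal(length(fx$truth$branch_rates), 31)
  # fixture bundle writes plain-text files
  d <- tempfile()
  make_wg_fixture(seed = 4, dir = d)
  expect_true(all(file.exists(file.path(d, c("fixture.nxs", "truth_tree.nwk",
                                             "truth_params.tsv",
                                             "candidates.nwk")))))
})
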