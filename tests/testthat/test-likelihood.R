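# Pruning likelihood against independent oracles, and parameter/branch
# optimization behavior.

test_that("pruning equals exhaustive enumeration on all 3 unrooted 4-taxon
           topologies", {
  set.seed(101)
  taxa <- c("a", "b", "c", "d")
  topos <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  aln <- random_alignment(4, 50, taxa = taxa)
  m <- ref_gtr()
  for (nwk in topos) {
    tr <- ape::read.tree(text = nwk)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
    expect_equal(tree_loglik(tr, aln, NULL, m)$loglik,
                 enum_loglik(tr, aln, m), tolerance = 1e-10)
  }
})

test_that("two-taxon Jukes-Cantor likelihood matches the closed form", {
  # k differing sites of n; p_diff(t) = 3/4 - 3/4 exp(-4t/3)
  n <- 40; k <- 9; t <- 0.25
  seqs <- c(a = paste(rep("A", n), collapse = ""),
            b = paste(c(rep("C", k), rep("A", n - k)), collapse = ""))
  aln <- tiny_alignment(seqs)
  tr <- ape::read.tree(text = "(a:0.15,b:0.1);")
  m <- gtr_model(ncat = 1)
  pd <- 3 / 4 - 3 / 4 * exp(-4 * t / 3)
  closed <- k * log(0.25 * pd / 3) + (n - k) * log(0.25 * (1 - pd))
  expect_equal(tree_loglik(tr, aln, NULL, m)$loglik, closed, tolerance = 1e-10)
})

test_that("all-missing column leaves total unchanged; sitewise sums to total", {
  set.seed(7)
  aln <- random_alignment(5, 60)
  tr <- random_tree(5)
  m <- ref_gtr()
  base <- tree_loglik(tr, aln, NULL, m)
  expect_equal(sum(base$sitewise), base$loglik, tolerance = 1e-6)
  aug <- alignment(cbind(aln$matrix, rep("?", 5)), taxa = aln$taxa)
  expect_equal(tree_loglik(tr, aug, NULL, m)$loglik, base$loglik,
               tolerance = 1e-9)
})

test_that("likelihood is invariant to taxon order and re-rooting", {
  set.seed(11)
  aln <- random_alignment(6, 80)
  tr <- random_tree(6)
  m <- ref_gtr()
  base <- tree_loglik(tr, aln, NULL, m)$loglik
  # shuffle alignment rows
  perm <- sample(6)
  aln2 <- alignment(aln$matrix[perm, ], taxa = aln$taxa[perm])
  expect_equal(tree_loglik(tr, aln2, NULL, m)$loglik, base, tolerance = 1e-8)
  # unrooted vs rooted representations of the same tree
  untr <- ape::unroot(tr)
  expect_equal(tree_loglik(untr, aln, NULL, m)$loglik, base, tolerance = 1e-8)
  rr <- ape::root(untr, outgroup = untr$tip.label[3], resolve.root = TRUE)
  expect_equal(tree_loglik(rr, aln, NULL, m)$loglik, base, tolerance = 1e-8)
})

test_that("partitioned total is the exact sum of per-partition totals", {
  set.seed(13)
  aln <- random_alignment(5, 90)
  tr <- random_tree(5)
  sch <- partition_scheme(list(a = 1:40, b = 41:90))
  models <- list(a = ref_gtr(), b = gtr_model(pinv = 0, alpha = 1))
  both <- tree_loglik(tr, aln, sch, models)
  expect_equal(both$loglik, sum(both$per_partition), tolerance = 1e-12)
  solo_a <- tree_loglik(tr, alignment(aln$matrix[, 1:40], taxa = aln$taxa),
                        NULL, models$a)$loglik
  expect_equal(unname(both$per_partition["a"]), solo_a, tolerance = 1e-9)
})

test_that("RY-coded partition likelihood equals the 2-state pruning oracle", {
  set.seed(17)
  taxa <- paste0("t", 1:4)
  m <- matrix(sample(c("R", "Y"), 4 * 40, replace = TRUE), 4,
              dimnames = list(taxa, NULL))
  aln <- alignment(m, taxa = taxa)
  tr <- random_tree(4)
  bm <- binary_model(c(0.6, 0.4), pinv = 0.1, alpha = 0.8)
  sch <- partition_scheme(list(ry = 1:40), encoding = "ry")
  expect_equal(tree_loglik(tr, aln, sch, list(ry = bm))$loglik,
               enum_loglik(tr, aln, bm), tolerance = 1e-9)
})

test_that("likelihood agrees with an independent ML implementation", {
  skip_if_not_installed("phangorn")
  set.seed(42)
  aln <- random_alignment(6, 200)
  tr <- random_tree(6)
  m <- ref_gtr()
  ours <- tree_loglik(tr, aln, NULL, m)$loglik
  fit <- phangorn::pml(tr, phangorn::phyDat(aln$matrix), bf = m$freqs,
                       Q = m$exch, inv = m$pinv, shape = m$alpha, k = 4)
  expect_equal(ours, fit$logLik, tolerance = 1e-6)
})

test_that("branch-length optimization: identical sequences collapse the tree,
           refitting from the optimum is a fixed point", {
  taxa <- paste0("t", 1:4)
  m0 <- matrix("A", 4, 30, dimnames = list(taxa, NULL))
  m0[, 1:10] <- "C"; m0[, 11:20] <- "G"
  aln_id <- alignment(m0, taxa = taxa)
  tr <- random_tree(4)
  f <- optimize_parameters(tr, aln_id, NULL, gtr_model(ncat = 1),
                           optimize_model = FALSE)
  expect_lt(max(f$edge_lengths), 1e-6)
  # fixed point on informative data
  set.seed(23)
  aln <- random_alignment(4, 150)
  f1 <- optimize_parameters(tr, aln, NULL, ref_gtr(), optimize_model = FALSE,
                            tol = 1e-6)
  f2 <- optimize_parameters(f1$tree, aln, NULL, ref_gtr(),
                            optimize_model = FALSE, tol = 1e-6)
  expect_lt(abs(f2$loglik - f1$loglik), 1e-3)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("simulated GTR+Gamma data recovers alpha and base frequencies", {
  # one long alignment on a fixed 8-taxon tree (module-scale recovery check)
  set.seed(77)
  tr <- ape::rcoal(8)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.4
  truth <- gtr_model(c(2, 6, 1, 1.5, 8, 1), c(0.32, 0.22, 0.18, 0.28),
                     pinv = 0, alpha = 0.5)
  spec <- simulation_spec(8, tree = chronogram(tr), partitions = list(
    p = list(length = 20000L, rate = 1, model = truth)), sigma = 0, seed = 78)
  aln <- simulate_alignment(chronogram(tr), spec)
  f <- suppressWarnings(optimize_parameters(tr, aln, NULL,
        gtr_model(freqs = empirical_frequencies(aln), pinv = 0.01, alpha = 1),
        tol = 1e-3, max_outer = 6))
  expect_lt(abs(f$models[[1]]$alpha - truth$alpha) / truth$alpha, 0.15)
  expect_lt(max(abs(empirical_frequencies(aln) - truth$freqs)), 0.02)
})
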