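# Sitewise matrices, RELL resampling, and the KH and AU tests.

test_that("sitewise rows sum to the tree totals and a single candidate has
           delta 0", {
  set.seed(41)
  tr <- ape::rcoal(6)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.4
  m <- ref_gtr(pinv = 0.05, alpha = 0.9)
  spec <- simulation_spec(6, tree = chronogram(tr), partitions = list(
    p = list(length = 800L, rate = 1, model = m)), sigma = 0, seed = 42)
  aln <- simulate_alignment(chronogram(tr), spec)
  sw1 <- sitewise_matrix(list(only = ape::unroot(tr)), aln, NULL,
                         models = list(all = m))
  expect_equal(unname(sw1$delta), 0)
  expect_equal(unname(rowSums(sw1$ll)), unname(sw1$totals), tolerance = 1e-9)
  # generating topology beats an NNI neighbour
  enc <- ratmito:::encode_tree(ratmito:::root_for_search(tr))
  alt <- ratmito:::nni_swap(enc$tree, ratmito:::nni_edges(enc$tree)[1], 1)
  sw <- sitewise_matrix(list(truth = tr, alt = alt), aln, NULL,
                        models = list(all = m))
  expect_equal(unname(sw$delta["truth"]), 0)
  expect_gt(unname(sw$delta["alt"]), 0)
})

test_that("candidate topology files round-trip with names", {
  cands <- fixture_candidates()[1:3]
  f <- tempfile(fileext = ".nwk")
  write_candidate_topologies(cands, f)
  back <- read_candidate_topologies(f)
  expect_named(back, names(cands))
  for (nm in names(cands))
    expect_same_topology(back[[nm]], cands[[nm]])
})

test_that("RELL resampling: determinism, consistency, single-site degeneracy", {
  set.seed(43)
  ll <- matrix(rnorm(3 * 120, -2, 0.4), 3, 120,
               dimnames = list(c("x", "y", "z"), NULL))
  r1 <- rell_resample(ll, n_reps = 600, seed = 9)
  r2 <- rell_resample(ll, n_reps = 600, seed = 9)
  expect_identical(r1, r2)
  # replicate means approach observed totals
  obs <- rowSums(ll)
  se <- apply(r1, 1, sd) / sqrt(ncol(r1))
  expect_true(all(abs(rowMeans(r1) - obs) < 3.5 * se + 1e-9))
  # one-site matrix: every replicate total is n_sites * that site's value
  one <- matrix(c(-1.5, -2.5), 2, 1, dimnames = list(c("u", "v"), NULL))
  ro <- rell_resample(one, n_reps = 20, seed = 1)
  expect_true(all(ro["u", ] == -1.5))
  expect_true(all(ro["v", ] == -2.5))
})

test_that("KH: identical rows give p 1; planted strong signal is rejected;
           near-null matrices keep p well calibrated", {
  ll <- synthetic_sitewise(nsites = 300, k = 40, lead = 0.6, seed = 3)
  same <- rbind(a = ll[1, ], b = ll[1, ])
  expect_equal(kh_test(same, "a", "b", n_reps = 200, seed = 1)$p, 1)
  strong <- kh_test(ll, "better", "worse", n_reps = 2000, seed = 2)
  expect_lt(strong$p, 0.01)
  expect_equal(strong$better, "better")
  # exchangeable-null rejection rate at alpha = 0.05 stays near nominal
  set.seed(4)
  rej <- 0
  for (i in 1:120) {
    d <- rnorm(150, 0, 0.3)
    mm <- rbind(a = d / 2, b = -d / 2)
    p <- kh_test(mm, "a", "b", n_reps = 400, seed = i)$p
    if (p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / 120, 0.09)
})

test_that("AU: unanimous winner gets p ~ 1, ML topology maximal, ordering
           weakly follows delta on exchangeable matrices", {
  set.seed(47)
  base <- matrix(rnorm(4 * 400, -2, 0.5), 4, 400,
                 dimnames = list(paste0("t", 1:4), NULL))
  base[2, ] <- base[1, ] - 0.002 + rnorm(400, 0, 0.05)
  base[3, ] <- base[1, ] - 0.01 + rnorm(400, 0, 0.05)
  base[4, ] <- base[1, ] - 0.05 + rnorm(400, 0, 0.05)
  res <- au_test(base, n_reps_per_scale = 2000, seed = 6)
  expect_true(all(res$p_au >= 0 & res$p_au <= 1))
  best <- which.min(res$delta)
  expect_equal(which.max(res$p_au), best)
  # clearly separated winner
  sep <- base; sep[1, ] <- sep[1, ] + 0.5
  res2 <- au_test(sep, n_reps_per_scale = 500, seed = 7)
  expect_gte(res2$p_au[1], 0.999)
  expect_error(au_test(base[1, , drop = FALSE]), "at least 2")
})

test_that("AU at scale 1 connects to KH: with a symmetric sitewise
           difference distribution the worse topology's bootstrap
           proportion matches its KH p", {
  # iid normal sitewise differences: the centered RELL null is symmetric, so
  # P(worse wins a resample) = P(centered delta exceeds the observed delta)
  set.seed(8)
  d <- rnorm(600, mean = 0.004, sd = 0.25)
  ll <- rbind(better = d / 2, worse = -d / 2)
  res <- au_test(ll, scales = c(0.8, 0.9, 1, 1.1, 1.2),
                 n_reps_per_scale = 6000, seed = 9)
  kh <- kh_test(ll, "better", "worse", n_reps = 6000, seed = 10)
  worse_row <- setdiff(c("better", "worse"), kh$better)
  bp_worse <- res$bp[res$topology == worse_row]
  expect_lt(abs(bp_worse - kh$p), 0.06)
})

test_that("site permutation leaves totals and deltas unchanged", {
  ll <- synthetic_sitewise(nsites = 250, k = 30, lead = 0.3, seed = 11)
  perm <- sample(ncol(ll))
  llp <- ll[, perm]
  expect_equal(rowSums(llp), rowSums(ll))
  r1 <- au_test(ll, n_reps_per_scale = 800, seed = 3)
  r2 <- au_test(llp, n_reps_per_scale = 800, seed = 3)
  expect_equal(r1$delta, r2$delta, tolerance = 1e-9)
  expect_lt(max(abs(r1$p_au - r2$p_au)), 0.06)
})
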