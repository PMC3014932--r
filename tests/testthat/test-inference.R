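# ML search, bootstrap support, and the window scan.

test_that("three taxa yield the unique unrooted topology", {
  set.seed(3)
  aln <- random_alignment(3, 200)
  res <- ml_search(aln, seed = 1)
  expect_equal(ape::Ntip(res$unrooted), 3)
  expect_true(is.finite(res$loglik))
})

test_that("search recovers the generating topology and is seed-deterministic", {
  set.seed(19)
  tr <- ape::rcoal(8)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.6
  m <- ref_gtr(pinv = 0.1, alpha = 0.8)
  spec <- simulation_spec(8, tree = chronogram(tr), partitions = list(
    p = list(length = 4000L, rate = 1, model = m)), sigma = 0, seed = 20)
  aln <- simulate_alignment(chronogram(tr), spec)
  res <- ml_search(aln, models = list(all = m), seed = 5)
  expect_same_topology(res$unrooted, tr)
  # restarting at the optimum returns the same topology and likelihood
  res2 <- ml_search(aln, models = list(all = m), start_tree = res$tree, seed = 5)
  expect_same_topology(res2$unrooted, res$unrooted)
  expect_equal(res2$loglik, res$loglik, tolerance = 1e-3)
  # deterministic given the seed
  res3 <- ml_search(aln, models = list(all = m), seed = 5)
  expect_equal(res3$loglik, res$loglik, tolerance = 1e-10)
  expect_error(ml_search(alignment(aln$matrix[1:2, ], taxa = aln$taxa[1:2])),
               "3 taxa")
})

test_that("strong exclusive signal gives near-unanimous bootstrap support and
           clade/complement symmetry", {
  set.seed(29)
  tr <- ape::read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1):0;")
  tr$edge.length <- tr$edge.length * 0.08
  m <- gtr_model(pinv = 0, alpha = Inf, ncat = 1)
  spec <- simulation_spec(8, tree = chronogram(tr), partitions = list(
    p = list(length = 1500L, rate = 1, model = m)), sigma = 0, seed = 30)
  aln <- simulate_alignment(chronogram(tr), spec)
  cl <- list(ab = c("a", "b"), abcd_comp = c("e", "f", "g", "h"),
             abcd = c("a", "b", "c", "d"))
  bs <- bootstrap_support(aln, models = list(all = m), n_reps = 40, seed = 2,
                          clades = cl)
  expect_gte(bs[["ab"]], 99)
  # a clade and its complement are the same bipartition
  expect_equal(bs[["abcd"]], bs[["abcd_comp"]])
  expect_error(bootstrap_support(aln, n_reps = 2, clades = list(x = "nope"),
                                 seed = 1), "unknown")
})

test_that("bootstrap replicates preserve column counts within partitions", {
  set.seed(31)
  aln <- random_alignment(4, 60)
  sch <- partition_scheme(list(a = 1:25, b = 26:60))
  rep_data <- ratmito:::resample_columns(aln, sch, partitioned = TRUE)
  expect_equal(ncol(rep_data$aln$matrix), 60)
  expect_equal(lengths(rep_data$scheme$partitions), c(a = 25L, b = 35L))
  rep2 <- ratmito:::resample_columns(aln, sch, partitioned = FALSE)
  expect_equal(ncol(rep2$aln$matrix), 60)
})

test_that("scan on an alignment shorter than the window equals plain
           bootstrap support", {
  set.seed(37)
  tr <- ape::rcoal(6)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.4
  m <- ref_gtr(pinv = 0, alpha = 1)
  spec <- simulation_spec(6, tree = chronogram(tr), partitions = list(
    p = list(length = 600L, rate = 1, model = m)), sigma = 0, seed = 38)
  aln <- simulate_alignment(chronogram(tr), spec)
  cl <- list(pair = ape::extract.clade(tr, ape::Ntip(tr) + 2)$tip.label)
  scan <- clade_frequency_scan(aln, cl, width = 1000, n_reps = 25, seed = 9)
  expect_equal(nrow(scan), 1)
  expect_equal(scan$width, 600)
  expect_true(scan$pair >= 0 && scan$pair <= 100)
})

test_that("support summaries annotate nodes and handle absent clades", {
  tr <- ape::read.tree(text = "((a,b),((c,d),e));")
  taxa <- tr$tip.label
  bs <- c(100, 87)
  names(bs) <- c(clade_key(c("a", "b"), taxa), clade_key(c("c", "d"), taxa))
  bpp <- c(1.0)
  names(bpp) <- clade_key(c("a", "b"), taxa)
  ann <- summarize_support(tr, bs, bpp)
  sup <- attr(ann, "support")
  # {a,b} and {c,d,e} are the same unrooted split, so both nodes carry it
  ab <- sup[sup$clade == clade_key(c("a", "b"), taxa), ]
  expect_true(all(ab$BS == 100))
  expect_true(all(ab$BPP == 1))
  cd <- sup[sup$clade == clade_key(c("c", "d"), taxa), ]
  expect_equal(cd$BS, 87)
  expect_equal(cd$BPP, 0) # absent from the posterior table
  # labels round-trip through newick
  txt <- ape::write.tree(ann)
  back <- ape::read.tree(text = txt)
  expect_true(any(grepl("100", back$node.label)))
})
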