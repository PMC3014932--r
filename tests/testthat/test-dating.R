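# Calibrations, tree priors, MCMC correctness on small cases, trace
# diagnostics, HPDs and MCC summaries.

test_that("calibration families reproduce their closed-form parameters", {
  # normal from central 95%: bounds 11..12.3
  cn <- make_calibration("normal-from-central95", c(11, 12.3))
  expect_equal(cn$p1, 11.65)
  expect_equal(cn$p2, (12.3 - 11) / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(cn$p2, 0.3316, tolerance = 1e-3)
  # uniform density
  cu <- make_calibration("uniform", c(11, 34))
  expect_equal(exp(cu$logdensity(20)), 1 / 23, tolerance = 1e-12)
  expect_equal(cu$logdensity(40), -Inf)
  expect_error(make_calibration("uniform", c(5, 2)), "inverted")
  # lognormal from median and CI: location ln(median), scale solves the CI
  cl <- make_calibration("lognormal-from-median-CI", c(2.7, 1.7, 3.9))
  expect_equal(cl$p1, log(2.7))
  # independent 1-D root-find oracle for the least-squares scale
  # stationary point of the least-squares objective, found by root-finding
  g <- function(s) (1.959964 * s - (log(2.7) - log(1.7))) -
                   ((log(3.9) - log(2.7)) - 1.959964 * s)
  oracle <- uniroot(g, c(1e-4, 2))$root
  expect_equal(cl$p2, oracle, tolerance = 1e-6)
  # densities integrate to 1
  expect_equal(integrate(function(t) exp(cn$logdensity(t)), 0, 50)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(function(t) exp(cl$logdensity(t)), 0, 100)$value, 1,
               tolerance = 1e-4)
})

test_that("tree priors: coalescent closed form, Yule limit, unit
           normalization for n = 2", {
  # 2-taxon coalescent with N = 1: density exp(-t)
  expect_equal(tree_prior_logdensity(1.3, tree_prior("coalescent", N = 1),
                                     ntip = 2), -1.3)
  # birth-death with death 0 equals the algebraic pure-birth form
  ages <- c(0.4, 1.1, 2.2)
  bd0 <- tree_prior_logdensity(ages, tree_prior("birth-death", birth = 0.7,
                                                death = 0), ntip = 4)
  yule <- sum(log(0.7) - 0.7 * ages)
  expect_equal(bd0, yule, tolerance = 1e-12)
  # n = 2 birth-death density integrates to 1 over the root age
  for (mu in c(0, 0.3)) {
    spec <- tree_prior("birth-death", birth = 1, death = mu)
    z <- integrate(function(t) sapply(t, function(ti)
      exp(tree_prior_logdensity(ti, spec, ntip = 2))), 0, Inf,
      rel.tol = 1e-9)$value
    expect_equal(z, 1, tolerance = 1e-6)
  }
  expect_error(tree_prior_logdensity(c(-1, 2), tree_prior(), ntip = 3),
               "negative")
  expect_error(tree_prior("birth-death", birth = 0.5, death = 0.7), "birth")
})

test_that("ESS matches iid, AR(1) and duplication oracles", {
  set.seed(53)
  x <- rnorm(10000)
  expect_true(ess(x) > 8000 && ess(x) < 12000)
  # AR(1), rho = 0.9: ESS ~ n (1-rho)/(1+rho)
  rho <- 0.9
  ar <- as.numeric(arima.sim(list(ar = rho), 20000))
  expect_equal(ess(ar), 20000 * (1 - rho) / (1 + rho), tolerance = 0.25)
  # duplicating every sample halves the information
  y <- rnorm(4000)
  dup <- rep(y, each = 2)
  # each sample twice: the ESS is about half the duplicated trace's length
  expect_equal(ess(dup) / length(dup), 0.5, tolerance = 0.2)
  cst <- ess(rep(3.2, 100))
  expect_equal(as.numeric(cst), 100)
  expect_true(attr(cst, "zero_variance"))
})

test_that("HPD interval: order statistics, degeneracy, and brute force", {
  x <- 1:100
  h <- hpd_interval(x, 0.95)
  expect_equal(h[2] - h[1], 94)
  expect_equal(hpd_interval(rep(5, 30)), c(5, 5))
  set.seed(59)
  s <- rexp(151)
  m <- ceiling(0.95 * length(s))
  xs <- sort(s)
  widths <- xs[m:length(s)] - xs[1:(length(s) - m + 1)]
  i <- which.min(widths)
  expect_equal(hpd_interval(s), c(xs[i], xs[i + m - 1]))
})

test_that("MCMC posterior matches a quadrature oracle on two taxa", {
  # strict clock, fixed rate: posterior of the root age is proportional to
  # exp(-t) * L(t); detailed balance of the sampler shows up as agreement
  set.seed(5)
  mu <- 0.05
  tr <- ape::read.tree(text = "(A:1.2,B:1.2);")
  chron <- chronogram(tr)
  spec <- simulation_spec(2, tree = chron, partitions = list(
    p = list(length = 800L, rate = mu, model = gtr_model())), sigma = 0,
    seed = 3)
  aln <- simulate_alignment(chron, spec)
  post <- run_dating_mcmc(aln, NULL, models = list(all = gtr_model(ncat = 1)),
    clock = clock_model("strict"), prior = tree_prior("coalescent", N = 1),
    start = chron,
    config = mcmc_config(generations = 150000, sample_every = 50, seed = 9,
                         topology_moves = FALSE, sample_mu = FALSE,
                         sample_model = FALSE, ncat = 1), mu0 = mu)
  s <- post$trace$root_age[-(1:300)]
  llt <- function(t) {
    tt <- tr; tt$edge.length <- c(mu * t, mu * t)
    tree_loglik(tt, aln, NULL, gtr_model(ncat = 1))$loglik
  }
  ts <- seq(0.005, 6, by = 0.01)
  lp <- sapply(ts, llt) - ts
  w <- exp(lp - max(lp)); w <- w / sum(w)
  expect_equal(mean(s), sum(ts * w), tolerance = 0.05)
  qcdf <- cumsum(w)
  thin <- s[seq(1, length(s), by = 5)]
  ks <- suppressWarnings(ks.test(thin, function(q)
    approx(ts, qcdf, q, rule = 2)$y))
  expect_gt(ks$p.value, 0.01)
})

test_that("posterior medians agree across independent seeds (overlapping
           HPDs) and all samples satisfy constraints/ultrametricity", {
  set.seed(61)
  tr <- ape::read.tree(text = "((a:1,b:1):1.5,(c:2,d:2):0.5);")
  chron <- chronogram(tr)
  m <- gtr_model(pinv = 0, alpha = 1)
  spec <- simulation_spec(4, tree = chron, partitions = list(
    p = list(length = 1200L, rate = 0.1, model = m)), sigma = 0.1, seed = 62)
  aln <- simulate_alignment(chron, spec)
  cal <- make_calibration("normal-from-central95", c(2.0, 3.0),
                          clade = aln$taxa)
  runs <- lapply(c(101, 202), function(sd)
    run_dating_mcmc(aln, NULL, models = list(all = m),
      clock = clock_model("ucln", sigma = 0.2),
      prior = tree_prior("birth-death", birth = 0.8, death = 0),
      calibrations = list(cal), constraints = list(c("a", "b")),
      tracked = list(ab = c("a", "b")),
      config = mcmc_config(generations = 60000, sample_every = 60, seed = sd)))
  h <- lapply(runs, function(r) hpd_interval(r$trace$tmrca_ab[-(1:200)]))
  expect_lt(max(h[[1]][1], h[[2]][1]), min(h[[1]][2], h[[2]][2]))
  # every sampled chronogram is ultrametric and keeps (a,b) monophyletic
  for (ch in runs[[1]]$trees[seq(1, 1000, by = 97)]) {
    depth <- ape::node.depth.edgelength(ch$tree)
    tipd <- depth[seq_len(4)]
    expect_lt(diff(range(tipd)), 1e-8)
    expect_true(!is.null(ape::getMRCA(ch$tree, c("a", "b"))))
    mrca_ab <- ape::getMRCA(ch$tree, c("a", "b"))
    expect_setequal(ape::extract.clade(ch$tree, mrca_ab)$tip.label, c("a", "b"))
  }
})

test_that("MCC tree: singleton, median ages, unanimity", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  ch <- chronogram(tr)
  single <- mcc_tree(list(ch), burnin = 0)
  expect_same_topology(single$tree, tr)
  expect_equal(max(single$ages), 2)
  # clade ages {1, 2, 9} -> median 2
  trees <- lapply(c(1, 2, 9), function(h) {
    t2 <- ape::read.tree(text = sprintf("((a:%g,b:%g):%g,c:%g);", h, h, 1,
                                        h + 1))
    chronogram(t2)
  })
  mcc <- mcc_tree(trees, burnin = 0)
  ab_node <- ape::getMRCA(mcc$tree, c("a", "b"))
  expect_equal(mcc$ages[ab_node], 2)
  expect_equal(mcc$pp, c(1, 1)) # all samples share the topology
})

test_that("relative node-depth scaling is pointwise multiplication", {
  r <- scale_relative_node_age(0.5, 10, c(8, 12))
  expect_equal(r$age, 5)
  expect_equal(r$ci, c(4, 6))
  r2 <- scale_relative_node_age(1, 7.3, c(6, 9))
  expect_equal(r2$age, 7.3)
  expect_equal(r2$ci, c(6, 9))
})

test_that("incompatible monophyly constraints are rejected before sampling", {
  set.seed(67)
  aln <- random_alignment(4, 50)
  expect_error(run_dating_mcmc(aln,
    constraints = list(c("t1", "t2"), c("t2", "t3")),
    config = mcmc_config(generations = 100, sample_every = 10, seed = 1)),
    "incompatible")
})
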