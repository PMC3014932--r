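# Bayesian relaxed-clock divergence dating: calibrations, tree priors,
# the MCMC front end (kernel in C++), trace diagnostics, HPDs and MCC trees.

#' Chronogram: a rooted, ultrametric, dated tree
#'
#' @param tree rooted binary `ape::phylo` with edge lengths in time units
#'   (Mya); tips at time 0.
#' @param tol ultrametricity tolerance (relative).
#' @return object of class `rm_chronogram` with `tree` and `ages` (vector of
#'   node ages indexed by ape node id; tips 0).
#' @export
chronogram <- function(tree, tol = 1e-6) {
  if (!ape::is.rooted(tree)) stop("chronogram requires a rooted tree")
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth)
  ages <- h - depth
  if (any(abs(ages[seq_len(ntip)]) > tol * max(h, 1)))
    stop("tree is not ultrametric")
  ages[seq_len(ntip)] <- 0
  structure(list(tree = tree, ages = ages), class = "rm_chronogram")
}

#' @export
print.rm_chronogram <- function(x, ...) {
  cat(sprintf("rm_chronogram: %d tips, root age %.4g\n",
              length(x$tree$tip.label), max(x$ages)))
  invisible(x)
}

#' Age of the most recent common ancestor of a taxon set
#' @param chron an `rm_chronogram`.
#' @param tips taxon labels.
#' @return numeric age.
#' @export
tmrca <- function(chron, tips) {
  node <- if (length(tips) == 1) match(tips, chron$tree$tip.label)
          else ape::getMRCA(chron$tree, tips)
  chron$ages[node]
}

#' Calibration prior on a clade age
#'
#' Three families, parameterized the way calibrations are reported:
#' \describe{
#'   \item{normal-from-central95}{`params = c(lo, hi)`: the bounds of the
#'     central 95% of a normal density (mean the midpoint,
#'     `sd = (hi - lo) / (2 * 1.959964)`), truncated at 0.}
#'   \item{uniform}{`params = c(lo, hi)`.}
#'   \item{lognormal-from-median-CI}{`params = c(median, lo, hi)`: log-scale
#'     location `log(median)`; scale the least-squares fit matching the
#'     central 95% interval to `[lo, hi]`, i.e.
#'     `(log(hi) - log(lo)) / (2 * 1.959964)`.}
#' }
#'
#' @param family one of the above.
#' @param params numeric parameters in Mya (see above).
#' @param clade taxon labels whose MRCA the calibration constrains.
#' @return object of class `rm_calibration` with a `logdensity` function.
#' @export
make_calibration <- function(family = c("normal-from-central95", "uniform",
                                        "lognormal-from-median-CI"),
                             params, clade = NULL) {
  family <- match.arg(family)
  z <- stats::qnorm(0.975)
  if (family == "uniform") {
    lo <- params[1]; hi <- params[2]
    if (hi <= lo) stop("inverted bounds")
    p1 <- lo; p2 <- hi
    ld <- function(t) ifelse(t >= lo & t <= hi, -log(hi - lo), -Inf)
  } else if (family == "normal-from-central95") {
    lo <- params[1]; hi <- params[2]
    if (hi <= lo) stop("inverted bounds")
    p1 <- (lo + hi) / 2
    p2 <- (hi - lo) / (2 * z)
    # truncated at 0 and renormalized: ages are non-negative
    lnorm_c <- stats::pnorm(0, p1, p2, lower.tail = FALSE, log.p = TRUE)
    ld <- function(t) ifelse(t >= 0, stats::dnorm(t, p1, p2, log = TRUE) - lnorm_c,
                             -Inf)
  } else {
    med <- params[1]; lo <- params[2]; hi <- params[3]
    if (hi <= lo || med <= 0) stop("invalid median/CI parameters")
    p1 <- log(med)
    p2 <- (log(hi) - log(lo)) / (2 * z)
    ld <- function(t) stats::dlnorm(t, p1, p2, log = TRUE)
  }
  structure(list(family = family, p1 = p1, p2 = p2, clade = clade,
                 logdensity = ld), class = "rm_calibration")
}

#' Derive a lognormal calibration from posterior age samples
#'
#' Used to carry a root-age posterior from one analysis into another as a
#' `lognormal-from-median-CI` prior (median and central 95% interval of the
#' samples).
#'
#' @param samples numeric age samples.
#' @param clade taxon labels for the calibrated clade.
#' @return an `rm_calibration`.
#' @export
calibration_from_samples <- function(samples, clade = NULL) {
  q <- stats::quantile(samples, c(0.5, 0.025, 0.975), names = FALSE)
  make_calibration("lognormal-from-median-CI", q, clade)
}

#' Tree prior specification
#' @param kind `"birth-death"` or `"coalescent"` (constant population size).
#' @param birth,death birth-death rates (per My); `death = 0` is pure birth.
#' @param N coalescent effective size (in the tree's time units).
#' @return object of class `rm_treeprior`.
#' @export
tree_prior <- function(kind = c("birth-death", "coalescent"), birth = 1,
                       death = 0, N = 1) {
  kind <- match.arg(kind)
  if (birth <= 0 || death < 0 || N <= 0) stop("rates/size must be positive")
  if (kind == "birth-death" && death >= birth)
    stop("birth-death prior requires birth > death")
  structure(list(kind = kind, birth = birth, death = death, N = N),
            class = "rm_treeprior")
}

#' Log-density of a dated tree under a tree prior
#'
#' Birth-death (conditioned on the number of tips): each internal node age
#' contributes `log(lambda * p1(t))` with
#' `p1(t) = (lambda-mu)^2 exp(-(lambda-mu) t) / (lambda - mu exp(-(lambda-mu) t))^2`;
#' with `death = 0` this reduces to the pure-birth (Yule) form.  Constant-size
#' coalescent: `sum_k [-k(k-1) tau_k / (2N)] - (n-1) log N` over inter-node
#' intervals.
#'
#' @param chron an `rm_chronogram` (or numeric vector of internal node ages
#'   when `ntip` is given).
#' @param spec an `rm_treeprior`.
#' @param ntip number of tips when `chron` is a plain age vector.
#' @return log-density (unnormalized over topologies; normalized over ages
#'   for the coalescent and for the birth-death with `n = 2`).
#' @export
tree_prior_logdensity <- function(chron, spec, ntip = NULL) {
  if (inherits(chron, "rm_chronogram")) {
    ntip <- length(chron$tree$tip.label)
    ages <- chron$ages[-seq_len(ntip)]
  } else {
    if (is.null(ntip)) stop("ntip required for a plain age vector")
    ages <- as.numeric(chron)
  }
  if (any(ages < 0)) stop("negative node age")
  if (spec$kind == "birth-death") {
    lam <- spec$birth; mu <- spec$death
    if (mu <= 0) return(sum(log(lam) - lam * ages))
    r <- lam - mu
    e <- exp(-r * ages)
    return(sum(log(lam) + 2 * log(r) - r * ages - 2 * log(lam - mu * e)))
  }
  ev <- sort(ages)
  n <- ntip
  k <- seq(n, 2)
  tau <- diff(c(0, ev))
  sum(-k * (k - 1) * tau / (2 * spec$N)) - (n - 1) * log(spec$N)
}

#' Relaxed (or strict) molecular clock specification
#' @param kind `"ucln"` (uncorrelated lognormal branch rates, mean 1, stdev
#'   `sigma` estimated) or `"strict"`.
#' @param sigma starting value of the log-scale rate stdev.
#' @param sigma_prior_rate rate of the exponential prior on `sigma`.
#' @return object of class `rm_clock`.
#' @export
clock_model <- function(kind = c("ucln", "strict"), sigma = 0.3,
                        sigma_prior_rate = 2) {
  kind <- match.arg(kind)
  structure(list(kind = kind, sigma = if (kind == "strict") 0 else sigma,
                 sigma_prior_rate = sigma_prior_rate), class = "rm_clock")
}

#' MCMC configuration for divergence dating
#' @param generations total proposals.
#' @param sample_every sampling interval.
#' @param burnin_frac fraction of samples discarded by the summaries (the
#'   trace itself is returned in full).
#' @param seed integer seed.
#' @param prior_only switch off the data term (sample from the prior).
#' @param topology_moves allow constrained subtree-exchange moves.
#' @param sample_mu,sample_model sample per-partition rate multipliers /
#'   substitution parameters (fixing them gives an empirical-Bayes run).
#' @param ncat gamma categories.
#' @return list of class `rm_mcmc_config`.
#' @export
mcmc_config <- function(generations = 200000L, sample_every = 100L,
                        burnin_frac = 0.1, seed = 1L, prior_only = FALSE,
                        topology_moves = TRUE, sample_mu = TRUE,
                        sample_model = TRUE, ncat = 4L) {
  stopifnot(generations >= sample_every, sample_every >= 1,
            burnin_frac >= 0, burnin_frac < 1)
  structure(list(generations = as.integer(generations),
                 sample_every = as.integer(sample_every),
                 burnin_frac = burnin_frac, seed = as.integer(seed),
                 prior_only = prior_only, topology_moves = topology_moves,
                 sample_mu = sample_mu, sample_model = sample_model,
                 ncat = as.integer(ncat)), class = "rm_mcmc_config")
}

# ---- starting chronogram -------------------------------------------------

# Average-linkage clustering whose merges respect monophyly constraints:
# a merge is allowed only if the union is nested within, contains, or is
# disjoint from every constraint set.  Heights are halved cophenetic
# distances, then rescaled so the root hits root_age.
constrained_upgma <- function(aln, constraints, root_age) {
  D <- as.matrix(pairwise_distance(aln))
  taxa <- aln$taxa
  n <- length(taxa)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n)
  trees <- as.list(taxa)
  sizes <- rep(1L, n)
  cons <- lapply(constraints, function(cl) match(cl, taxa))
  ok_merge <- function(u) {
    for (cm in cons) {
      i <- length(intersect(u, cm))
      if (i > 0 && i < length(cm) && i < length(u)) return(FALSE)
    }
    TRUE
  }
  cd <- function(a, b) mean(D[clusters[[a]], clusters[[b]]])
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL; bd <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1)) {
      a <- active[ii]; b <- active[jj]
      if (!ok_merge(c(clusters[[a]], clusters[[b]]))) next
      d <- cd(a, b)
      if (d < bd) { bd <- d; best <- c(a, b) }
    }
    if (is.null(best)) stop("constraints are incompatible with any tree")
    a <- best[1]; b <- best[2]
    h <- max(bd / 2, heights[a] + 1e-9, heights[b] + 1e-9)
    newid <- length(clusters) + 1L
    clusters[[newid]] <- c(clusters[[a]], clusters[[b]])
    heights[newid] <- h
    trees[[newid]] <- sprintf("(%s:%g,%s:%g)", trees[[a]], h - heights[a],
                              trees[[b]], h - heights[b])
    active <- c(setdiff(active, best), newid)
  }
  txt <- paste0(trees[[active]], ";")
  tr <- ape::read.tree(text = txt)
  ch <- chronogram(tr, tol = 1e-3)
  s <- root_age / max(ch$ages)
  tr$edge.length <- tr$edge.length * s
  chronogram(tr, tol = 1e-3)
}

# encode a chronogram for the kernel
chron_kernel_tree <- function(chron) {
  tr <- chron$tree
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  parent <- integer(nnode); left <- integer(nnode); right <- integer(nnode)
  for (v in (ntip + 1):nnode) {
    kids <- tr$edge[tr$edge[, 1] == v, 2]
    if (length(kids) != 2) stop("dating requires a rooted binary tree")
    left[v] <- kids[1]; right[v] <- kids[2]
  }
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  root <- ntip + 1L
  parent[root] <- 0L
  list(ntip = ntip, nnode = nnode, root = root, parent = parent,
       left = left, right = right, age = chron$ages, tip.label = tr$tip.label)
}

#' Bayesian relaxed-clock divergence dating
#'
#' Metropolis-Hastings sampling of node ages, branch-rate multipliers, the
#' clock stdev, per-partition rate multipliers and substitution parameters,
#' and (optionally) topology within monophyly constraints.  Calibrated nodes
#' take their calibration density in place of the birth-death per-node
#' factor; every sampled tree satisfies all constraints.
#'
#' @param aln an `rm_alignment`.
#' @param scheme `rm_scheme` or `NULL`.
#' @param models starting models (`NULL`: [default_models()] with empirical
#'   frequencies; frequencies stay fixed during the run).
#' @param clock an [clock_model()].
#' @param prior an [tree_prior()].
#' @param calibrations list of [make_calibration()] objects with `clade` set.
#' @param constraints list of taxon-label vectors kept monophyletic (clades
#'   of calibrations are constrained automatically).
#' @param start optional starting `rm_chronogram`; default is a
#'   constraint-respecting average-linkage tree scaled to the first
#'   calibration's central age.
#' @param config an [mcmc_config()].
#' @param tracked named list of extra taxon sets whose MRCA ages are traced.
#' @param mu0 starting per-partition rate multipliers (subs/site/My);
#'   default is a crude distance-based guess shared by all partitions.
#' @return object of class `rm_posterior`: `trace` (data frame), `trees`
#'   (list of sampled `rm_chronogram`s), `accept` (per-move acceptance),
#'   `taxa`, `config`.
#' @export
run_dating_mcmc <- function(aln, scheme = NULL, models = NULL,
                            clock = clock_model(), prior = tree_prior(),
                            calibrations = list(), constraints = list(),
                            start = NULL, config = mcmc_config(),
                            tracked = list(), mu0 = NULL) {
  if (is.null(scheme))
    scheme <- partition_scheme(list(all = seq_len(ncol(aln$matrix))))
  if (is.null(models)) models <- default_models(aln, scheme)
  # constraints: calibrated clades are automatically enforced
  cal_clades <- lapply(calibrations, `[[`, "clade")
  cal_clades <- cal_clades[!vapply(cal_clades, is.null, TRUE)]
  all_cons <- unique(c(constraints, cal_clades))
  all_cons <- all_cons[vapply(all_cons, function(x)
    length(x) > 1 && length(x) < length(aln$taxa), TRUE)]
  check_constraint_compat(all_cons, aln$taxa)
  # starting state
  root_guess <- if (length(calibrations)) {
    ca <- calibrations[[1]]
    switch(ca$family, uniform = (ca$p1 + ca$p2) / 2,
           `normal-from-central95` = ca$p1, exp(ca$p1))
  } else 1
  if (is.null(start)) start <- constrained_upgma(aln, all_cons, root_guess)
  kt <- chron_kernel_tree(start)
  # nudge calibrated node ages toward their calibration centers
  kt <- nudge_calibrated_ages(kt, calibrations, start)
  taxa <- kt$tip.label
  if (is.null(mu0)) {
    dbar <- mean(as.matrix(pairwise_distance(aln)))
    mu0 <- max(dbar / (2 * max(kt$age)), 1e-5)
  }
  mu0 <- rep_len(mu0, length(scheme$partitions))
  parts <- lapply(seq_along(scheme$partitions), function(i) {
    pd <- partition_data(aln, scheme$partitions[[i]], scheme$encoding[[i]],
                         taxa = taxa)
    m <- models[[i]]
    list(tipp = pd$tipp, patw = pd$patw, freqs = m$freqs,
         invlik = invariant_lik(pd, m$freqs),
         exch = if (m$kind == "gtr") m$exch else numeric(0),
         alpha = min(ifelse(is.finite(m$alpha), m$alpha, 10), 50),
         pinv = min(max(m$pinv, 1e-3), 0.79), mu = mu0[i],
         sample_exch = m$kind == "gtr")
  })
  cal_list <- lapply(calibrations, function(ca) {
    list(tips = match(ca$clade, taxa),
         family = match(ca$family, c("uniform", "normal-from-central95",
                                     "lognormal-from-median-CI")) - 1L,
         p1 = ca$p1, p2 = ca$p2,
         replace = prior$kind == "birth-death")
  })
  cons_list <- lapply(all_cons, match, taxa)
  cal_names <- if (length(cal_clades)) paste0("cal", seq_along(cal_clades))
               else character(0)
  track_all <- c(stats::setNames(cal_clades, cal_names), tracked)
  track_list <- lapply(track_all, match, taxa)
  kclock <- list(relaxed = clock$kind == "ucln", sigma = max(clock$sigma, 0.05),
                 sigma_prior_rate = clock$sigma_prior_rate,
                 rates = rep(1, kt$nnode))
  kprior <- list(kind = if (prior$kind == "birth-death") 0L else 1L,
                 birth = prior$birth, death = prior$death, N = prior$N,
                 mu_meanlog = log(mu0[1]), mu_sdlog = 2)
  kconfig <- list(generations = config$generations,
                  sample_every = config$sample_every,
                  prior_only = config$prior_only,
                  topology_moves = config$topology_moves && length(taxa) > 3,
                  sample_mu = config$sample_mu,
                  sample_model = config$sample_model,
                  ncat = config$ncat, tracked = track_list)
  res <- with_seed(config$seed,
    cpp_dating_mcmc(kt, parts, kclock, kprior, cal_list, cons_list, kconfig))
  np <- length(parts)
  cn <- c("state", "lnL", "lnPrior", "sigma", "root_age",
          paste0("mu_", names(scheme$partitions)),
          paste0("alpha_", names(scheme$partitions)),
          paste0("pinv_", names(scheme$partitions)),
          if (length(track_list)) paste0("tmrca_", names(track_list)))
  trace <- as.data.frame(res$trace)
  names(trace) <- cn
  trees <- rebuild_chronograms(res, kt)
  structure(list(trace = trace, trees = trees,
                 accept = data.frame(
                   move = c("age", "root", "rate", "sigma", "mu", "alpha",
                            "pinv", "exch", "topology", "subtree_scale"),
                   proposed = as.numeric(res$proposed),
                   accepted = as.numeric(res$accept)),
                 taxa = taxa, config = config, scheme = scheme),
            class = "rm_posterior")
}

check_constraint_compat <- function(cons, taxa) {
  for (i in seq_along(cons)) {
    bad <- setdiff(cons[[i]], taxa)
    if (length(bad)) stop("constraint names unknown taxa: ",
                          paste(bad, collapse = ", "))
    for (j in seq_len(i - 1)) {
      a <- cons[[i]]; b <- cons[[j]]
      k <- length(intersect(a, b))
      if (k > 0 && k < length(a) && k < length(b))
        stop("incompatible monophyly constraints (partial overlap)")
    }
  }
  invisible(TRUE)
}

nudge_calibrated_ages <- function(kt, calibrations, start) {
  for (ca in calibrations) {
    if (is.null(ca$clade)) next
    target <- switch(ca$family, uniform = (ca$p1 + ca$p2) / 2,
                     `normal-from-central95` = ca$p1, exp(ca$p1))
    node <- if (length(ca$clade) == length(kt$tip.label)) kt$root
            else ape::getMRCA(start$tree, ca$clade)
    lo <- max(kt$age[c(kt$left[node], kt$right[node])])
    hi <- if (kt$parent[node] > 0) kt$age[kt$parent[node]] else Inf
    kt$age[node] <- min(max(target, lo * 1.01 + 1e-6), ifelse(is.finite(hi), hi * 0.99, target))
  }
  # enforce parent > child strictly after nudging
  ord <- order(kt$age[(kt$ntip + 1):kt$nnode]) + kt$ntip
  for (v in ord) {
    lo <- max(kt$age[c(kt$left[v], kt$right[v])])
    if (kt$age[v] <= lo) kt$age[v] <- lo + max(1e-6, 0.01 * lo)
  }
  kt
}

rebuild_chronograms <- function(res, kt) {
  nsamp <- nrow(res$ages)
  ntip <- kt$ntip
  lapply(seq_len(nsamp), function(i) {
    par <- res$parent[i, ]
    ages <- c(rep(0, ntip), res$ages[i, ])
    child <- which(par > 0)
    edge <- cbind(par[child], child)
    tr <- list(edge = edge, tip.label = kt$tip.label, Nnode = kt$nnode - ntip,
               edge.length = ages[edge[, 1]] - ages[edge[, 2]])
    class(tr) <- "phylo"
    tr <- stats::reorder(tr, "postorder")
    structure(list(tree = tr, ages = ages), class = "rm_chronogram")
  })
}

#' Effective sample size of an MCMC trace
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at
#' the first non-positive pair (Geyer's initial positive sequence).
#'
#' @param trace numeric vector (length >= 10).
#' @param max_lag autocorrelation lags examined.
#' @return ESS; a constant trace returns `n` with attribute
#'   `zero_variance = TRUE`.
#' @export
ess <- function(trace, max_lag = min(length(trace) - 1, 2000L)) {
  n <- length(trace)
  if (n < 10) stop("trace too short for ESS")
  if (stats::var(trace) == 0)
    return(structure(as.numeric(n), zero_variance = TRUE))
  rho <- stats::acf(trace, lag.max = max_lag, plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' samples.
#'
#' @param samples numeric vector (>= 20 values).
#' @param mass probability mass.
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 20) stop("need at least 20 samples for an HPD interval")
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

# rooted clade keys of a chronogram (tip sets, sorted labels)
rooted_clades <- function(chron) {
  tr <- chron$tree
  ntip <- length(tr$tip.label)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"), "")
  ages <- chron$ages[seq_along(pp) + ntip]
  stats::setNames(ages, keys)
}

#' Maximum clade credibility chronogram
#'
#' Among the post-burnin sampled topologies, picks the one maximizing the
#' product of posterior clade probabilities; node heights are the medians of
#' each clade's sampled ages, with 95% HPD intervals and clade probabilities
#' attached.
#'
#' @param samples an `rm_posterior` or list of `rm_chronogram`s.
#' @param burnin fraction (or count) of initial samples discarded.
#' @return an `rm_chronogram` with extra fields `hpd` (2 x nodes), `pp`
#'   (posterior clade probability per internal node) and `clade_ages`.
#' @export
mcc_tree <- function(samples, burnin = 0.1) {
  trees <- if (inherits(samples, "rm_posterior")) samples$trees else samples
  nb <- if (burnin < 1) floor(burnin * length(trees)) else as.integer(burnin)
  trees <- trees[(nb + 1):length(trees)]
  if (!length(trees)) stop("no post-burnin samples")
  claded <- lapply(trees, rooted_clades)
  all_keys <- unique(unlist(lapply(claded, names)))
  counts <- table(factor(unlist(lapply(claded, names)), levels = all_keys))
  pp <- as.numeric(counts) / length(trees)
  names(pp) <- all_keys
  score <- vapply(claded, function(cl) sum(log(pp[names(cl)])), 0)
  best <- which.max(score)
  chron <- trees[[best]]
  ntip <- length(chron$tree$tip.label)
  bestcl <- claded[[best]]
  agelist <- lapply(names(bestcl), function(k)
    unlist(lapply(claded, function(cl) cl[[k]])))
  names(agelist) <- names(bestcl)
  med <- vapply(agelist, stats::median, 0)
  hpds <- vapply(agelist, function(a)
    if (length(a) >= 20) hpd_interval(a) else range(a), numeric(2))
  # map clade keys back to node ids of the MCC topology
  keyed <- rooted_clades(chron)
  node_keys <- names(keyed)
  ages <- chron$ages
  pp_node <- numeric(length(node_keys))
  hpd <- matrix(NA_real_, 2, ntip + length(node_keys))
  for (i in seq_along(node_keys)) {
    k <- node_keys[i]
    ages[ntip + i] <- med[[k]]
    hpd[, ntip + i] <- hpds[, k]
    pp_node[i] <- pp[[k]]
  }
  tr <- chron$tree
  # rebuild edge lengths from median ages
  tr$edge.length <- ages[tr$edge[, 1]] - ages[tr$edge[, 2]]
  structure(list(tree = tr, ages = ages, hpd = hpd, pp = pp_node,
                 clade_ages = agelist), class = "rm_chronogram")
}

#' Scale a relative node depth by a dated reference node
#'
#' Converts a node's relative depth (as a fraction of a dated reference
#' node's depth) into an absolute age, scaling the reference's interval
#' endpoints by the same fraction.
#'
#' @param depth_fraction fraction in (0, 1].
#' @param reference_age reference node age (> 0).
#' @param reference_ci numeric `c(lower, upper)` for the reference.
#' @return list with `age` and `ci`.
#' @export
scale_relative_node_age <- function(depth_fraction, reference_age,
                                    reference_ci = NULL) {
  stopifnot(depth_fraction > 0, depth_fraction <= 1, reference_age > 0)
  list(age = depth_fraction * reference_age,
       ci = if (is.null(reference_ci)) NULL else depth_fraction * reference_ci)
}

#' Write an MCC chronogram as a NEXUS tree with HPD comments
#' @param chron an `rm_chronogram` from [mcc_tree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mcc_nexus <- function(chron, path) {
  tr <- chron$tree
  ntip <- length(tr$tip.label)
  lab <- vapply(seq_len(tr$Nnode), function(i) {
    v <- ntip + i
    if (!is.null(chron$hpd) && !anyNA(chron$hpd[, v]))
      sprintf("[&age_median=%.4g,age_hpd={%.4g,%.4g},posterior=%.3g]",
              chron$ages[v], chron$hpd[1, v], chron$hpd[2, v],
              if (!is.null(chron$pp)) chron$pp[i] else NA)
    else ""
  }, "")
  tr$node.label <- lab
  txt <- ape::write.tree(tr)
  writeLines(c("#NEXUS", "BEGIN TREES;",
               paste0("  TREE mcc = ", txt), "END;"), path)
  invisible(path)
}

#' Write an MCMC trace as TSV
#' @param posterior an `rm_posterior`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(posterior, path) {
  utils::write.table(posterior$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
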