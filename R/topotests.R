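# Candidate-topology evaluation: sitewise log-likelihood matrices, RELL
# resampling, and the Kishino-Hasegawa and approximately-unbiased tests.

#' Read a named multi-Newick candidate topology file
#'
#' Each line holds one tree, optionally prefixed by a `[name]` comment;
#' unnamed trees are called `tree1`, `tree2`, ...
#'
#' @param path file path.
#' @return named list of `ape::phylo` objects over identical leaf sets.
#' @export
read_candidate_topologies <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    nm <- sub("^\\[([^]]*)\\].*$", "\\1", lines[i])
    if (nm == lines[i]) nm <- paste0("tree", i)
    txt <- sub("^\\[[^]]*\\]\\s*", "", lines[i])
    out[[nm]] <- ape::read.tree(text = txt)
  }
  check_leafsets(out)
  out
}

#' Write candidate topologies as a named multi-Newick file
#' @param candidates named list of `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_topologies <- function(candidates, path) {
  lines <- vapply(seq_along(candidates), function(i)
    paste0("[", names(candidates)[i], "] ",
           ape::write.tree(candidates[[i]])), "")
  writeLines(lines, path)
  invisible(path)
}

check_leafsets <- function(candidates) {
  if (anyDuplicated(names(candidates))) stop("duplicate topology names")
  ls1 <- sort(candidates[[1]]$tip.label)
  for (nm in names(candidates))
    if (!identical(sort(candidates[[nm]]$tip.label), ls1))
      stop("topology ", nm, " has a different leaf set")
  invisible(TRUE)
}

#' Sitewise log-likelihood matrix over candidate topologies
#'
#' For every candidate, branch lengths are optimized per partition (each
#' partition run separately, as in the combined-partition test workflow) with
#' model parameters held at values fitted once on the first candidate (or
#' supplied).  Row sums equal the trees' total log-likelihoods.
#'
#' @param candidates named list of `ape::phylo` over the alignment's taxa.
#' @param aln an `rm_alignment`.
#' @param scheme `rm_scheme` or `NULL`.
#' @param models per-partition models; `NULL` fits them on the first
#'   candidate.
#' @param tol,brent_tol optimization tolerances.
#' @return object of class `rm_sitewise`: list with `ll` (topologies x
#'   sites), `totals`, `delta` (log-likelihood differences to the best), and
#'   `models`.
#' @export
sitewise_matrix <- function(candidates, aln, scheme = NULL, models = NULL,
                            tol = 1e-3, brent_tol = 1e-6) {
  check_leafsets(candidates)
  if (!setequal(candidates[[1]]$tip.label, aln$taxa))
    stop("candidate leaf set does not match alignment taxa")
  if (is.null(scheme))
    scheme <- partition_scheme(list(all = seq_len(ncol(aln$matrix))))
  if (is.null(models)) {
    f <- suppressWarnings(
      optimize_parameters(candidates[[1]], aln, scheme,
                          default_models(aln, scheme), tol = 0.01,
                          max_outer = 4L, brent_tol = brent_tol))
    models <- f$models
  }
  n <- ncol(aln$matrix)
  ll <- matrix(NA_real_, length(candidates), n,
               dimnames = list(names(candidates), NULL))
  for (nm in names(candidates)) {
    fit <- optimize_parameters(candidates[[nm]], aln, scheme, models,
                               optimize_model = FALSE, tol = tol,
                               brent_tol = brent_tol)
    sw <- tree_loglik(fit$tree, aln, scheme, models,
                      edge_lengths = fit$edge_lengths)
    ll[nm, ] <- sw$sitewise
  }
  totals <- rowSums(ll)
  structure(list(ll = ll, totals = totals, delta = max(totals) - totals,
                 models = models), class = "rm_sitewise")
}

#' @export
print.rm_sitewise <- function(x, ...) {
  cat(sprintf("rm_sitewise: %d topologies x %d sites\n", nrow(x$ll), ncol(x$ll)))
  print(round(cbind(lnL = x$totals, delta = x$delta), 2))
  invisible(x)
}

# RELL resample counts for one chunk: site indices drawn with replacement,
# tabulated into a dense count matrix (much faster than rmultinom at genome
# scale)
rell_counts <- function(nsites, n_reps, m) {
  cnt <- matrix(0, nsites, n_reps)
  for (j in seq_len(n_reps))
    cnt[, j] <- tabulate(sample.int(nsites, m, replace = TRUE), nsites)
  cnt
}

#' RELL resampling of sitewise log-likelihoods
#'
#' Site columns are resampled with replacement (no re-optimization) and
#' per-replicate total log-likelihoods are returned for every topology.
#'
#' @param matrix an `rm_sitewise` (or a plain topologies x sites matrix).
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @param m sites drawn per replicate (default the original number).
#' @return topologies x n_reps matrix of replicate totals.
#' @export
rell_resample <- function(matrix, n_reps = 10000L, seed = 1L, m = NULL) {
  ll <- if (inherits(matrix, "rm_sitewise")) matrix$ll else matrix
  n <- ncol(ll)
  if (is.null(m)) m <- n
  with_seed(seed, {
    out <- base::matrix(NA_real_, nrow(ll), n_reps, dimnames = list(rownames(ll), NULL))
    done <- 0L
    while (done < n_reps) {
      chunk <- min(250L, n_reps - done)
      cnt <- rell_counts(n, chunk, m)
      out[, done + seq_len(chunk)] <- ll %*% cnt
      done <- done + chunk
    }
    out
  })
}

#' Kishino-Hasegawa paired-sites test of two topologies
#'
#' The observed log-likelihood difference between the better and the worse
#' topology is compared to a centered RELL null distribution; the returned
#' p value is one-sided for the worse topology.
#'
#' @param matrix an `rm_sitewise` or plain matrix with both topologies.
#' @param topoA,topoB topology names (or row indices).
#' @param n_reps RELL replicates.
#' @param seed integer seed.
#' @return list with `p`, `delta` (observed difference, >= 0), `better`.
#' @export
kh_test <- function(matrix, topoA, topoB, n_reps = 10000L, seed = 1L) {
  ll <- if (inherits(matrix, "rm_sitewise")) matrix$ll else matrix
  a <- ll[topoA, ]; b <- ll[topoB, ]
  dsite <- a - b
  D <- sum(dsite)
  if (identical(topoA, topoB) || isTRUE(all.equal(a, b)))
    return(list(p = 1, delta = 0, better = NA_character_))
  better <- if (D >= 0) topoA else topoB
  dsite <- if (D >= 0) dsite else -dsite
  delta <- abs(D)
  reps <- rell_resample(rbind(d = dsite), n_reps = n_reps, seed = seed)[1, ]
  centered <- reps - mean(reps)
  p <- mean(centered >= delta)
  list(p = p, delta = delta, better = as.character(better))
}

#' Approximately unbiased (AU) test via multiscale RELL bootstrap
#'
#' For each relative sample size r, the bootstrap proportion of each topology
#' being best is probit-transformed and a weighted least-squares fit
#' `z(r) = d*sqrt(r) + c/sqrt(r)` yields `p_AU = 1 - Phi(d - c)` per
#' topology.  Bootstrap proportions of exactly 0 or 1 are clamped to
#' `1/(2*n_reps)` before the probit transform; a topology that is best in
#' every replicate at every scale gets `p_AU` of essentially 1.
#'
#' @param matrix an `rm_sitewise` or plain topologies x sites matrix.
#' @param scales relative sample sizes (should span 1).
#' @param n_reps_per_scale RELL replicates per scale.
#' @param seed integer seed.
#' @return data frame with topology, lnL, delta, bp (proportion best at
#'   scale 1), p_au; multiscale details in attribute `"bp"`.
#' @export
au_test <- function(matrix, scales = seq(0.5, 1.4, by = 0.1),
                    n_reps_per_scale = 10000L, seed = 1L) {
  ll <- if (inherits(matrix, "rm_sitewise")) matrix$ll else matrix
  ntopo <- nrow(ll); n <- ncol(ll)
  if (ntopo < 2) stop("au_test needs at least 2 candidate topologies")
  B <- n_reps_per_scale
  bp <- matrix(0, ntopo, length(scales), dimnames = list(rownames(ll), NULL))
  for (si in seq_along(scales)) {
    m <- max(1L, round(scales[si] * n))
    reps <- rell_resample(ll, n_reps = B, seed = seed + 7L * si, m = m)
    best <- max.col(t(reps), ties.method = "first")
    tab <- tabulate(best, nbins = ntopo)
    bp[, si] <- tab / B
  }
  eps <- 1 / (2 * B)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  p_au <- numeric(ntopo)
  for (i in seq_len(ntopo)) {
    if (all(bp[i, ] >= 1 - .Machine$double.eps)) { p_au[i] <- 1; next }
    if (all(bp[i, ] <= 0)) { p_au[i] <- 2 * eps; next }
    z <- stats::qnorm(1 - bpc[i, ])
    sr <- sqrt(scales)
    X <- cbind(sr, 1 / sr)
    w <- B * stats::dnorm(z)^2 / (bpc[i, ] * (1 - bpc[i, ]))
    fit <- stats::lm.wfit(X, z, w)
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    p_au[i] <- 1 - stats::pnorm(d - cc)
  }
  totals <- rowSums(ll)
  out <- data.frame(topology = rownames(ll), lnL = totals,
                    delta = max(totals) - totals,
                    bp = bp[, which.min(abs(scales - 1))], p_au = p_au,
                    row.names = NULL)
  attr(out, "bp") <- bp
  attr(out, "scales") <- scales
  out
}

#' Run KH and AU together over a candidate set
#'
#' @param matrix an `rm_sitewise`.
#' @param n_reps RELL replicates per scale (KH uses the same count).
#' @param seed integer seed.
#' @param scales AU relative sample sizes.
#' @return data frame: topology, lnL, delta, p_au, p_kh (KH of each topology
#'   against the maximum-likelihood topology; the ML topology itself gets
#'   p_kh 1).
#' @export
topology_tests <- function(matrix, n_reps = 10000L, seed = 1L,
                           scales = seq(0.5, 1.4, by = 0.1)) {
  au <- au_test(matrix, scales = scales, n_reps_per_scale = n_reps, seed = seed)
  best <- au$topology[which.min(au$delta)]
  p_kh <- vapply(au$topology, function(tp) {
    if (tp == best) return(1)
    kh_test(matrix, best, tp, n_reps = n_reps, seed = seed)$p
  }, 0)
  au$p_kh <- as.numeric(p_kh)
  au
}

#' Write topology test results as TSV
#' @param results data frame from [topology_tests()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topotest_tsv <- function(results, path) {
  utils::write.table(results[, intersect(c("topology", "lnL", "delta", "p_au",
                                           "p_kh"), names(results))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
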