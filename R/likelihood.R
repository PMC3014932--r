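# Partitioned phylogenetic likelihood: data preparation in R, pruning and
# branch-length optimization in the C++ kernel (src/kernel.cpp).

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `-` = c("A", "C", "G", "T"), `?` = c("A", "C", "G", "T"))

char_partial <- function(ch, encoding) {
  if (encoding == "nucleotide") {
    states <- c("A", "C", "G", "T")
    s <- iupac_sets[[ch]]
    if (is.null(s)) s <- states
  } else {
    states <- c("R", "Y")
    s <- switch(ch, R = "R", A = "R", G = "R",
                Y = "Y", C = "Y", T = "Y", U = "Y", c("R", "Y"))
  }
  as.numeric(states %in% s)
}

# Compress an alignment block into site patterns and tip partial likelihoods.
# Returns tipp (k x npat x ntip, tips in `taxa` order), patw, site_pattern.
partition_data <- function(aln, columns, encoding = "nucleotide", taxa = aln$taxa) {
  k <- if (encoding == "nucleotide") 4L else 2L
  block <- aln$matrix[taxa, columns, drop = FALSE]
  key <- apply(block, 2, paste0, collapse = "")
  upat <- unique(key)
  site_pattern <- match(key, upat)
  patw <- as.numeric(tabulate(site_pattern, nbins = length(upat)))
  ntip <- length(taxa)
  tipp <- array(0, dim = c(k, length(upat), ntip))
  first <- match(upat, key)
  for (i in seq_len(ntip)) {
    chars <- block[i, first]
    for (u in unique(chars)) {
      p <- char_partial(u, encoding)
      tipp[, which(chars == u), i] <- p
    }
  }
  list(tipp = tipp, patw = patw, site_pattern = site_pattern, k = k,
       npat = length(upat), ntip = ntip, taxa = taxa, columns = columns,
       encoding = encoding)
}

# pi-weighted likelihood of each pattern being an invariant site
invariant_lik <- function(pdata, freqs) {
  prodmat <- pdata$tipp[, , 1]
  if (pdata$ntip > 1)
    for (i in 2:pdata$ntip) prodmat <- prodmat * pdata$tipp[, , i]
  if (pdata$npat == 1) prodmat <- matrix(prodmat, ncol = 1)
  as.numeric(crossprod(freqs, prodmat))
}

# Encode an ape phylo (rooted or unrooted; unrooted basal multifurcation is
# handled directly) for the kernel.  Tip order = tree$tip.label.
encode_tree <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  list(eparent = tree$edge[, 1], echild = tree$edge[, 2],
       elen = if (is.null(tree$edge.length)) rep(0.1, nrow(tree$edge))
              else tree$edge.length,
       nnode = length(tree$tip.label) + tree$Nnode,
       ntip = length(tree$tip.label),
       root = length(tree$tip.label) + 1L,
       tip.label = tree$tip.label, tree = tree)
}

model_kernel_args <- function(model) {
  g <- discretize_gamma(model$alpha, model$ncat)
  # variable-site rates rescaled by 1/(1-pinv): branch lengths then count
  # expected substitutions per site overall (the PAUP*/RAxML convention)
  list(Q = build_rate_matrix(model), pi = model$freqs,
       catrate = g$rates / (1 - model$pinv), catw = g$weights,
       pinv = model$pinv)
}

#' Partitioned log-likelihood of a tree with sitewise output
#'
#' Felsenstein-pruning likelihood under the `+I+Gamma` mixture
#' `L = pinv * L_inv + (1 - pinv) * mean_c L(rate_c)`; gaps and `?` integrate
#' over all states, IUPAC ambiguities over their state subsets.  Partitions
#' are computed independently (one model each) and the total is the exact sum
#' of per-partition totals.
#'
#' @param tree an `ape::phylo` covering all alignment taxa, with branch
#'   lengths in expected substitutions per site.
#' @param aln an `rm_alignment`.
#' @param scheme an `rm_scheme`; `NULL` treats the alignment as one
#'   nucleotide partition.
#' @param models a single `rm_model` or a named list, one per partition.
#' @param edge_lengths optional matrix (edges x partitions, rows following
#'   `reorder(tree, "postorder")$edge`) of unlinked per-partition branch
#'   lengths; default uses `tree$edge.length` for every partition.
#' @return list with `loglik`, `sitewise` (per alignment column, original
#'   order), and `per_partition` totals.
#' @export
tree_loglik <- function(tree, aln, scheme = NULL, models, edge_lengths = NULL) {
  if (!setequal(tree$tip.label, aln$taxa))
    stop("tree taxa and alignment taxa differ")
  if (is.null(scheme))
    scheme <- partition_scheme(list(all = seq_len(ncol(aln$matrix))))
  if (inherits(models, "rm_model"))
    models <- stats::setNames(rep(list(models), length(scheme$partitions)),
                              names(scheme$partitions))
  enc <- encode_tree(tree)
  sitewise <- rep(NA_real_, ncol(aln$matrix))
  per_part <- stats::setNames(numeric(length(scheme$partitions)),
                              names(scheme$partitions))
  for (ip in seq_along(scheme$partitions)) {
    nm <- names(scheme$partitions)[ip]
    cols <- scheme$partitions[[nm]]
    model <- models[[nm]]
    if (is.null(model)) stop("no model for partition ", nm)
    pd <- partition_data(aln, cols, scheme$encoding[[nm]], taxa = enc$tip.label)
    ka <- model_kernel_args(model)
    elen <- if (is.null(edge_lengths)) enc$elen else edge_lengths[, nm]
    patll <- cpp_partition_sitewise(enc$eparent, enc$echild, elen, enc$nnode,
                                    enc$ntip, enc$root, pd$tipp, ka$Q, ka$pi,
                                    ka$catrate, ka$catw, ka$pinv,
                                    invariant_lik(pd, ka$pi))
    sitewise[cols] <- patll[pd$site_pattern]
    per_part[nm] <- sum(patll * pd$patw)
  }
  list(loglik = sum(per_part), sitewise = sitewise, per_partition = per_part)
}

# parameter transforms for model optimization
model_to_par <- function(model, estimate_freqs) {
  p <- c(log_alpha = log(min(model$alpha, 100)),
         t_pinv = stats::qlogis(max(model$pinv, 1e-4) / 0.95))
  if (model$kind == "gtr") p <- c(p, log_exch = log(pmax(model$exch[1:5], 1e-6)))
  if (estimate_freqs) p <- c(p, log_f = log(model$freqs[-model$k] / model$freqs[model$k]))
  p
}

par_to_model <- function(p, model, estimate_freqs) {
  model$alpha <- exp(p[["log_alpha"]])
  model$pinv <- 0.95 * stats::plogis(p[["t_pinv"]])
  if (model$kind == "gtr")
    model$exch <- c(exp(p[grep("^log_exch", names(p))]), 1)
  if (estimate_freqs) {
    lf <- p[grep("^log_f", names(p))]
    f <- c(exp(lf), 1)
    model$freqs <- f / sum(f)
  }
  model
}

fit_one_partition <- function(enc, pd, model, elen, optimize_model,
                              estimate_freqs, tol, max_outer, brent_tol) {
  ll_prev <- -Inf
  converged <- FALSE
  part_ll <- function(m, lens) {
    ka <- model_kernel_args(m)
    patll <- cpp_partition_sitewise(enc$eparent, enc$echild, lens, enc$nnode,
                                    enc$ntip, enc$root, pd$tipp, ka$Q, ka$pi,
                                    ka$catrate, ka$catw, ka$pinv,
                                    invariant_lik(pd, ka$pi))
    sum(patll * pd$patw)
  }
  for (it in seq_len(max_outer)) {
    ka <- model_kernel_args(model)
    fit <- cpp_fit_blens(enc$eparent, enc$echild, elen, enc$nnode, enc$ntip,
                         enc$root, pd$tipp, pd$patw, ka$Q, ka$pi, ka$catrate,
                         ka$catw, ka$pinv, invariant_lik(pd, ka$pi),
                         tol, 8L, 1e-8, 20, brent_tol)
    elen <- fit$edge_length
    ll <- fit$loglik
    if (optimize_model) {
      if (it == 1) {
        # coarse grid over the weakly identified (alpha, pinv) pair avoids
        # stalling on their likelihood ridge
        grid <- expand.grid(alpha = c(0.2, 0.4, 0.8, 1.5, 3),
                            pinv = c(0.01, 0.15, 0.3, 0.5, 0.7))
        gl <- apply(grid, 1, function(g) {
          m <- model; m$alpha <- g[["alpha"]]; m$pinv <- g[["pinv"]]
          part_ll(m, elen)
        })
        best <- which.max(gl)
        model$alpha <- grid$alpha[best]
        model$pinv <- grid$pinv[best]
      }
      obj <- function(p) -part_ll(par_to_model(p, model, estimate_freqs), elen)
      p0 <- model_to_par(model, estimate_freqs)
      op <- stats::optim(p0, obj, method = "Nelder-Mead",
                         control = list(maxit = 600, reltol = 1e-10))
      model <- par_to_model(op$par, model, estimate_freqs)
      ll <- -op$value
    }
    if (ll - ll_prev < tol && it > 1) { converged <- TRUE; break }
    ll_prev <- ll
  }
  list(model = model, elen = elen, loglik = ll, converged = converged)
}

#' Fit substitution-model parameters and branch lengths on a fixed topology
#'
#' Partitions are unlinked: each gets its own branch lengths and model
#' parameters (the partitioned analyses this package reproduces run each
#' partition separately).  Branch lengths are optimized by bracketed
#' per-branch line search; model parameters by Nelder-Mead on transformed
#' coordinates; the two are alternated until the log-likelihood gain per
#' full pass falls below `tol`.
#'
#' @param tree `ape::phylo` topology (branch lengths used as start values).
#' @param aln an `rm_alignment`.
#' @param scheme `rm_scheme` (or `NULL` for a single nucleotide partition).
#' @param models initial model(s), as in [tree_loglik()].
#' @param optimize_model if `FALSE`, only branch lengths are fitted.
#' @param estimate_freqs also estimate stationary frequencies (default uses
#'   the initial model's, typically empirical).
#' @param tol convergence tolerance in log-likelihood units per pass.
#' @param max_outer maximum alternation rounds per partition.
#' @param brent_tol branch-length line-search tolerance.
#' @return list with fitted `models`, `edge_lengths` (edges x partitions,
#'   postorder rows), `loglik`, `per_partition`, `tree` (postorder, with the
#'   first partition's lengths), and `converged`.
#' @export
optimize_parameters <- function(tree, aln, scheme = NULL, models,
                                optimize_model = TRUE, estimate_freqs = FALSE,
                                tol = 1e-4, max_outer = 10L, brent_tol = 1e-6) {
  if (is.null(scheme))
    scheme <- partition_scheme(list(all = seq_len(ncol(aln$matrix))))
  if (inherits(models, "rm_model"))
    models <- stats::setNames(rep(list(models), length(scheme$partitions)),
                              names(scheme$partitions))
  enc <- encode_tree(tree)
  enc$elen <- rescale_start_lengths(enc, aln)
  nparts <- length(scheme$partitions)
  elens <- matrix(NA_real_, length(enc$elen), nparts,
                  dimnames = list(NULL, names(scheme$partitions)))
  fitted <- models
  per_part <- stats::setNames(numeric(nparts), names(scheme$partitions))
  conv <- logical(nparts)
  for (ip in seq_len(nparts)) {
    nm <- names(scheme$partitions)[ip]
    pd <- partition_data(aln, scheme$partitions[[nm]], scheme$encoding[[nm]],
                         taxa = enc$tip.label)
    f <- fit_one_partition(enc, pd, models[[nm]], enc$elen, optimize_model,
                           estimate_freqs, tol, max_outer, brent_tol)
    fitted[[nm]] <- f$model
    elens[, ip] <- f$elen
    per_part[nm] <- f$loglik
    conv[ip] <- f$converged
  }
  out_tree <- enc$tree
  out_tree$edge.length <- elens[, 1]
  if (!all(conv))
    warning("parameter optimization did not fully converge; best-so-far returned")
  list(models = fitted, edge_lengths = elens, loglik = sum(per_part),
       per_partition = per_part, tree = out_tree, converged = all(conv))
}

# Rescale starting branch lengths so the mean root-to-tip depth matches half
# the mean pairwise distance: protects the optimizer when the supplied tree
# is on another scale (e.g. a time-calibrated chronogram).
rescale_start_lengths <- function(enc, aln) {
  el <- enc$elen
  depth <- numeric(enc$nnode)
  ne <- length(enc$eparent)
  for (e in rev(seq_len(ne)))
    depth[enc$echild[e]] <- depth[enc$eparent[e]] + el[e]
  md <- mean(depth[seq_len(enc$ntip)])
  if (md <= 0) return(pmin(pmax(el, 1e-6), 5))
  target <- mean(pairwise_distance(aln)) / 2
  f <- max(target, 1e-4) / md
  if (f > 0.5 && f < 2) f <- 1 # already on the substitution scale
  pmin(pmax(el * f, 1e-6), 5)
}

#' Default models for a scheme: GTR+I+Gamma4 with empirical frequencies for
#' nucleotide partitions, the binary model for RY partitions
#' @param aln an `rm_alignment`.
#' @param scheme an `rm_scheme`.
#' @param pinv,alpha starting values shared by all partitions.
#' @return named list of `rm_model` objects.
#' @export
default_models <- function(aln, scheme, pinv = 0.2, alpha = 0.7) {
  out <- list()
  for (nm in names(scheme$partitions)) {
    enc <- scheme$encoding[[nm]]
    fr <- empirical_frequencies(aln, scheme$partitions[[nm]], enc)
    fr <- (fr + 1e-3) / sum(fr + 1e-3)
    out[[nm]] <- if (enc == "ry") binary_model(fr, pinv, alpha)
                 else gtr_model(freqs = fr, pinv = pinv, alpha = alpha)
  }
  out
}
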