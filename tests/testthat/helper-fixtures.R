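# Shared test helpers: tiny alignments, reference models, and a brute-force
# likelihood oracle that sums over all internal-node state assignments.

tiny_alignment <- function(seqs) alignment(as.list(seqs))

ref_gtr <- function(pinv = 0.15, alpha = 0.6) {
  gtr_model(exch = c(1.5, 4, 0.8, 1.2, 5, 1), freqs = c(0.3, 0.2, 0.3, 0.2),
            pinv = pinv, alpha = alpha)
}

random_alignment <- function(ntaxa, ncols, taxa = paste0("t", seq_len(ntaxa))) {
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * ncols, replace = TRUE),
              ntaxa, ncols, dimnames = list(taxa, NULL))
  alignment(m, taxa = taxa)
}

random_tree <- function(ntaxa, min_len = 0.05, max_len = 0.3) {
  tr <- ape::rtree(ntaxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), min_len, max_len)
  tr
}

# exhaustive-enumeration log-likelihood: sums over every assignment of states
# to internal nodes, mixing invariant and gamma classes exactly as the model
# specifies (variable-site rates carry the 1/(1-pinv) rescaling)
enum_loglik <- function(tree, aln, model) {
  Q <- build_rate_matrix(model)
  states <- if (model$k == 4) c("A", "C", "G", "T") else c("R", "Y")
  g <- discretize_gamma(model$alpha, model$ncat)
  cr <- g$rates / (1 - model$pinv)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  seqs <- aln$matrix[tr$tip.label, , drop = FALSE]
  total <- 0
  intn <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(model$k)), length(intn))))
  for (s in seq_len(ncol(seqs))) {
    obs <- match(seqs[, s], states)
    inv_ok <- if (length(unique(obs)) == 1) model$freqs[obs[1]] else 0
    Ls <- 0
    for (ci in seq_along(cr)) {
      P <- lapply(seq_len(nrow(tr$edge)), function(e)
        transition_probability(model, tr$edge.length[e] * cr[ci], Q = Q))
      lik <- 0
      for (gi in seq_len(nrow(grid))) {
        st <- integer(nn)
        st[seq_len(ntip)] <- obs
        st[intn] <- grid[gi, ]
        p <- model$freqs[st[ntip + 1]]
        for (e in seq_len(nrow(tr$edge)))
          p <- p * P[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
        lik <- lik + p
      }
      Ls <- Ls + (1 - model$pinv) * g$weights[ci] * lik
    }
    total <- total + log(Ls + model$pinv * inv_ok)
  }
  total
}

# small planted-signal sitewise matrix: `better` leads on `k` strong sites
synthetic_sitewise <- function(nsites = 200, k = 30, lead = 0.5, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    base <- matrix(rnorm(2 * nsites, mean = -3, sd = 0.3), 2, nsites,
                   dimnames = list(c("better", "worse"), NULL))
    base[2, seq_len(k)] <- base[1, seq_len(k)] - lead
    base
  })
}

expect_same_topology <- function(t1, t2) {
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0)
}
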