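# ML topology search (NNI hill climbing), nonparametric bootstrap, and the
# genome-window clade-support scan.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# JC-corrected pairwise distances; RY-coded columns contribute as two-state
# mismatches.  Used only for neighbor-joining start trees.
pairwise_distance <- function(aln) {
  X <- aln$matrix
  X[X == "U"] <- "T"
  n <- nrow(X)
  valid <- matrix(X %in% c("A", "C", "G", "T", "R", "Y"), n)
  D <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- valid[i, ] & valid[j, ]
    p <- if (any(ok)) mean(X[i, ok] != X[j, ok]) else 0
    d <- if (p < 0.7425) -0.75 * log(1 - 4 * p / 3) else 5
    D[i, j] <- D[j, i] <- d
  }
  stats::as.dist(D)
}

# Neighbor-joining start tree, rooted on the first taxon for the search
# representation (likelihood is rooting-invariant under reversible models).
start_tree_nj <- function(aln) {
  if (length(aln$taxa) == 3) {
    tr <- ape::read.tree(text = sprintf("(%s,%s,%s);", aln$taxa[1], aln$taxa[2],
                                        aln$taxa[3]))
    tr$edge.length <- rep(0.05, 3)
    return(root_for_search(tr))
  }
  tr <- ape::nj(pairwise_distance(aln))
  tr$edge.length[tr$edge.length < 1e-6] <- 1e-6
  root_for_search(tr)
}

root_for_search <- function(tree) {
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.05, nrow(tree$edge))
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  stats::reorder(tree, "postorder")
}

# internal edges eligible for NNI: child internal, parent internal non-root
nni_edges <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ch <- tree$edge[, 2]
  pa <- tree$edge[, 1]
  ch[ch > ntip & pa != root]
}

# swap the sibling of v with one of v's children (variant 1 or 2)
nni_swap <- function(tree, v, variant) {
  pa <- tree$edge[, 1]; ch <- tree$edge[, 2]
  u <- pa[ch == v]
  sib <- ch[pa == u & ch != v]
  kids <- ch[pa == v]
  cc <- kids[variant]
  tree$edge[ch == sib, 1] <- v
  tree$edge[ch == cc, 1] <- u
  attr(tree, "order") <- NULL # edge rows are no longer sorted
  stats::reorder(tree, "postorder")
}

fit_all_blens <- function(enc, pds, kas, len_by_child, tol, passes, brent_tol) {
  total <- 0
  for (p in seq_along(pds)) {
    elen <- len_by_child[enc$echild, p]
    fit <- cpp_fit_blens(enc$eparent, enc$echild, elen, enc$nnode, enc$ntip,
                         enc$root, pds[[p]]$tipp, pds[[p]]$patw, kas[[p]]$Q,
                         kas[[p]]$pi, kas[[p]]$catrate, kas[[p]]$catw,
                         kas[[p]]$pinv, kas[[p]]$invlik, tol, passes, 1e-8, 20,
                         brent_tol)
    len_by_child[enc$echild, p] <- fit$edge_length
    total <- total + fit$loglik
  }
  list(len = len_by_child, loglik = total)
}

score_candidate <- function(cand, pds, kas, len_by_child, v, brent_tol) {
  enc <- encode_tree(cand)
  total <- 0
  for (p in seq_along(pds)) {
    elen <- len_by_child[enc$echild, p]
    r <- cpp_opt_edge(enc$eparent, enc$echild, elen, enc$nnode, enc$ntip,
                      enc$root, pds[[p]]$tipp, pds[[p]]$patw, kas[[p]]$Q,
                      kas[[p]]$pi, kas[[p]]$catrate, kas[[p]]$catw,
                      kas[[p]]$pinv, kas[[p]]$invlik, v, 1e-8, 20, brent_tol)
    total <- total + r$loglik
  }
  total
}

#' Maximum-likelihood tree search by NNI hill climbing
#'
#' Starts from a neighbor-joining tree (or a supplied topology), fits branch
#' lengths per partition (unlinked), then repeatedly scores all
#' nearest-neighbor interchanges by optimizing the central branch of each
#' candidate and accepts the first improvement found in a seeded deterministic
#' edge order, refitting all branch lengths after each accepted move.
#'
#' @param aln an `rm_alignment` with at least 3 taxa.
#' @param scheme `rm_scheme` or `NULL` (single nucleotide partition).
#' @param models fitted models per partition; `NULL` fits
#'   [default_models()] on the start tree and then holds them fixed during
#'   the topology search.
#' @param start_tree optional `ape::phylo` start topology.
#' @param seed integer seed controlling the edge traversal order (the search
#'   is deterministic given the seed).
#' @param tol branch-length refit tolerance (log-likelihood units).
#' @param brent_tol line-search tolerance on branch lengths.
#' @param max_moves cap on accepted rearrangements.
#' @return list with `tree` (rooted representation; `unrooted` gives the
#'   unrooted view), `loglik`, `models`, `edge_lengths` (node x partition,
#'   indexed by child node), and `n_moves`.
#' @export
ml_search <- function(aln, scheme = NULL, models = NULL, start_tree = NULL,
                      seed = 1L, tol = 1e-2, brent_tol = 1e-5, max_moves = 50L) {
  if (length(aln$taxa) < 3) stop("ml_search needs at least 3 taxa")
  if (is.null(scheme))
    scheme <- partition_scheme(list(all = seq_len(ncol(aln$matrix))))
  tree <- if (is.null(start_tree)) start_tree_nj(aln)
          else root_for_search(start_tree)
  if (!setequal(tree$tip.label, aln$taxa)) stop("start tree taxa mismatch")
  if (is.null(models)) {
    f <- suppressWarnings(
      optimize_parameters(tree, aln, scheme, default_models(aln, scheme),
                          tol = 0.1, max_outer = 3L, brent_tol = 1e-4))
    models <- f$models
    tree <- f$tree
  }
  enc <- encode_tree(tree)
  pds <- lapply(seq_along(scheme$partitions), function(i)
    c(partition_data(aln, scheme$partitions[[i]], scheme$encoding[[i]],
                     taxa = enc$tip.label)))
  kas <- lapply(seq_along(scheme$partitions), function(i) {
    ka <- model_kernel_args(models[[i]])
    ka$invlik <- invariant_lik(pds[[i]], ka$pi)
    ka
  })
  nnode <- enc$nnode
  len_by_child <- matrix(0.05, nnode, length(pds))
  len_by_child[enc$echild, ] <- enc$elen
  fit <- fit_all_blens(enc, pds, kas, len_by_child, tol, 6L, brent_tol)
  len_by_child <- fit$len
  cur <- fit$loglik
  n_moves <- 0L
  with_seed(seed, {
    repeat {
      improved <- FALSE
      edges <- nni_edges(enc$tree)
      if (!length(edges)) break
      edges <- edges[sample.int(length(edges))]
      for (v in edges) {
        for (variant in 1:2) {
          cand <- nni_swap(enc$tree, v, variant)
          sc <- score_candidate(cand, pds, kas, len_by_child, v, brent_tol)
          if (sc > cur + 1e-3) {
            enc <- encode_tree(cand)
            fit <- fit_all_blens(enc, pds, kas, len_by_child, tol, 4L, brent_tol)
            len_by_child <- fit$len
            cur <- fit$loglik
            n_moves <- n_moves + 1L
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (!improved || n_moves >= max_moves) break
    }
  })
  out_tree <- enc$tree
  out_tree$edge.length <- len_by_child[enc$echild, 1]
  list(tree = out_tree, unrooted = ape::unroot(out_tree), loglik = cur,
       models = models, edge_lengths = len_by_child, n_moves = n_moves)
}

#' Canonical key of an unrooted bipartition
#'
#' The side of the split not containing the reference taxon (the first of
#' `all_taxa`), sorted and joined; clade and complement therefore share a key.
#'
#' @param tips taxon labels on one side of the split.
#' @param all_taxa all taxon labels.
#' @return character key.
#' @export
clade_key <- function(tips, all_taxa) {
  bad <- setdiff(tips, all_taxa)
  if (length(bad)) stop("unknown taxa in clade: ", paste(bad, collapse = ", "))
  if (all_taxa[1] %in% tips) tips <- setdiff(all_taxa, tips)
  paste(sort(tips), collapse = "|")
}

# all bipartition keys displayed by a tree
tree_split_keys <- function(tree, all_taxa) {
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx)
    clade_key(attr(pp, "labels")[idx], all_taxa), "")
  unique(keys)
}

#' Clade frequencies across a list of trees
#' @param trees list of `ape::phylo` over the same taxa.
#' @param all_taxa taxon labels (defines the split canonicalization).
#' @return named numeric vector of clade frequencies in `[0, 1]`, keyed as in
#'   [clade_key()].
#' @export
clade_support_table <- function(trees, all_taxa) {
  tab <- table(unlist(lapply(trees, tree_split_keys, all_taxa = all_taxa)))
  out <- as.numeric(tab) / length(trees)
  names(out) <- names(tab)
  out
}

#' Nonparametric bootstrap support for chosen clades
#'
#' Columns are resampled with replacement (within partitions when a scheme is
#' given, across the whole alignment otherwise), the ML tree is re-estimated
#' on each replicate with the supplied models held fixed, and each clade's
#' support is the percentage of replicate best trees displaying its
#' bipartition.
#'
#' @param aln an `rm_alignment`.
#' @param scheme `rm_scheme` or `NULL`.
#' @param models per-partition models; `NULL` fits them once on the original
#'   alignment's NJ tree.
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed integer; replicate `i` uses `seed + i`.
#' @param clades named list of taxon-label vectors (clades are interpreted as
#'   unrooted bipartitions; a clade and its complement get equal support).
#' @param partitioned resample within partitions (default when a scheme with
#'   more than one partition is given).
#' @return named numeric vector of support percentages in `[0, 100]`, with the
#'   replicate tree list in attribute `"trees"`.
#' @export
bootstrap_support <- function(aln, scheme = NULL, models = NULL, n_reps = 100L,
                              seed = 1L, clades,
                              partitioned = !is.null(scheme)) {
  stopifnot(n_reps >= 1)
  if (is.null(scheme))
    scheme <- partition_scheme(list(all = seq_len(ncol(aln$matrix))))
  keys <- vapply(clades, clade_key, "", all_taxa = aln$taxa)
  if (is.null(models)) {
    f <- suppressWarnings(
      optimize_parameters(start_tree_nj(aln), aln, scheme,
                          default_models(aln, scheme),
                          tol = 0.1, max_outer = 3L, brent_tol = 1e-4))
    models <- f$models
  }
  counts <- stats::setNames(numeric(length(clades)), names(clades))
  trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep_data <- with_seed(seed + r, resample_columns(aln, scheme, partitioned))
    res <- ml_search(rep_data$aln, rep_data$scheme, models, seed = seed + r)
    trees[[r]] <- res$unrooted
    present <- tree_split_keys(res$tree, aln$taxa)
    counts <- counts + as.numeric(keys %in% present)
  }
  out <- 100 * counts / n_reps
  attr(out, "trees") <- trees
  out
}

resample_columns <- function(aln, scheme, partitioned) {
  if (partitioned && length(scheme$partitions) > 1) {
    cols <- integer(0); labs <- character(0); encs <- character(0)
    newparts <- list()
    at <- 0L
    for (nm in names(scheme$partitions)) {
      p <- scheme$partitions[[nm]]
      s <- sample(p, length(p), replace = TRUE)
      cols <- c(cols, s)
      newparts[[nm]] <- seq(at + 1L, at + length(p))
      at <- at + length(p)
    }
    sc <- partition_scheme(newparts, scheme$encoding)
  } else {
    nc <- ncol(aln$matrix)
    cols <- sample(nc, nc, replace = TRUE)
    sc <- partition_scheme(stats::setNames(list(seq_len(nc)),
                                           names(scheme$partitions)[1]),
                           scheme$encoding[1])
  }
  list(aln = alignment(aln$matrix[, cols, drop = FALSE], taxa = aln$taxa),
       scheme = sc)
}

#' Clade support scanned along the genome in non-overlapping windows
#'
#' Each window is analysed as a single unpartitioned nucleotide alignment
#' under GTR+I+Gamma: the model is fitted once per window, then an ML
#' bootstrap tabulates each clade's support.  Because the clades are counted
#' independently, compatible clades can sum to more than 100% in a window.
#'
#' @param aln an `rm_alignment`.
#' @param clades named list of taxon vectors.
#' @param width window width in columns.
#' @param n_reps bootstrap replicates per window.
#' @param seed integer seed; windows use derived seeds.
#' @param min_width windows narrower than this are flagged (`partial` column).
#' @return data frame with start, end, width, partial, and one support column
#'   (percent) per clade.
#' @export
clade_frequency_scan <- function(aln, clades, width = 1000L, n_reps = 100L,
                                 seed = 1L, min_width = width %/% 2L) {
  windows <- window_slice(aln, width)
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    bs <- bootstrap_support(w, scheme = NULL, models = NULL, n_reps = n_reps,
                            seed = seed + 1000L * i, clades = clades,
                            partitioned = FALSE)
    data.frame(start = attr(w, "start"), end = attr(w, "end"),
               width = attr(w, "width"),
               partial = attr(w, "width") < min_width,
               rbind(bs), check.names = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Annotate a tree's internal nodes with bootstrap and posterior support
#'
#' @param tree `ape::phylo` (the reference topology).
#' @param bootstrap_freqs named vector of bootstrap percentages keyed as in
#'   [clade_support_table()] (percent scale), or `NULL`.
#' @param posterior_clade_probs named vector of posterior clade probabilities
#'   in `[0, 1]`, keyed the same way, or `NULL`.
#' @return the tree with `node.label` set to `"BS/BPP"`; clades absent from a
#'   table get 0.  A `support` data frame is attached as an attribute.
#' @export
summarize_support <- function(tree, bootstrap_freqs = NULL,
                              posterior_clade_probs = NULL) {
  taxa <- tree$tip.label
  ntip <- length(taxa)
  tr <- stats::reorder(tree, "postorder")
  keys <- character(tr$Nnode)
  for (v in seq_len(tr$Nnode) + ntip) {
    tipset <- ape::extract.clade(tr, v)$tip.label
    keys[v - ntip] <- clade_key(tipset, taxa)
  }
  bs <- if (is.null(bootstrap_freqs)) rep(NA_real_, length(keys))
        else ifelse(keys %in% names(bootstrap_freqs),
                    bootstrap_freqs[keys], 0)
  bpp <- if (is.null(posterior_clade_probs)) rep(NA_real_, length(keys))
         else ifelse(keys %in% names(posterior_clade_probs),
                     posterior_clade_probs[keys], 0)
  lab <- paste0(ifelse(is.na(bs), "", sprintf("%g", round(bs))),
                "/", ifelse(is.na(bpp), "", sprintf("%.2f", bpp)))
  tr$node.label <- lab
  attr(tr, "support") <- data.frame(clade = keys, BS = as.numeric(bs),
                                    BPP = as.numeric(bpp))
  tr
}
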