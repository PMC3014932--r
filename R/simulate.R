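# Synthetic data with the statistical structure the pipeline assumes:
# dated trees, lognormal relaxed-clock branch rates, and partitioned
# substitution simulation (codon positions, RNA stems/loops, a hypervariable
# control-region stand-in).  No indels: alignments are generated aligned.

#' Simulation specification
#'
#' @param n_taxa number of tips (used when simulating a birth-death tree).
#' @param tree either `NULL` (simulate from `birth`/`death`) or a fixed
#'   `rm_chronogram` / newick string with ages (passed through unchanged).
#' @param birth,death birth-death rates per My for tree simulation.
#' @param partitions named list; each element a list with `length` (columns),
#'   `model` (an `rm_model`) and `rate` (substitutions/site/My multiplier).
#' @param sigma stdev of the lognormal relaxed clock (mean-1 branch rates);
#'   0 gives a strict clock.
#' @param seed integer seed (mandatory; per-partition streams are derived
#'   from it so partitions can be regenerated independently).
#' @return list of class `rm_simspec`.
#' @export
simulation_spec <- function(n_taxa = 16L, tree = NULL, birth = 1, death = 0,
                            partitions, sigma = 0.15, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(vapply(partitions, function(p) p$length > 0 && p$rate > 0, TRUE)),
            sigma >= 0)
  structure(list(n_taxa = as.integer(n_taxa), tree = tree, birth = birth,
                 death = death, partitions = partitions, sigma = sigma,
                 seed = as.integer(seed)), class = "rm_simspec")
}

#' Simulate (or pass through) a dated ultrametric tree
#'
#' Birth-death simulation conditions on the number of tips
#' (via `ape::rphylo`); a fixed tree in the spec is returned unchanged.
#'
#' @param spec an [simulation_spec()].
#' @return an `rm_chronogram` with `spec$n_taxa` leaves.
#' @export
simulate_chronogram <- function(spec) {
  if (!is.null(spec$tree)) {
    tr <- spec$tree
    if (is.character(tr)) tr <- chronogram(ape::read.tree(text = tr))
    if (inherits(tr, "phylo")) tr <- chronogram(tr)
    return(tr)
  }
  if (spec$n_taxa < 2) stop("need at least 2 taxa")
  tr <- with_seed(spec$seed,
                  ape::rphylo(spec$n_taxa, birth = spec$birth,
                              death = spec$death))
  chronogram(tr, tol = 1e-4)
}

# evolve one partition's states down the tree; returns ntip x length matrix
evolve_partition <- function(chron, model, rate_mult, branch_rates, length) {
  Q <- build_rate_matrix(model)
  states <- if (model$k == 4) c("A", "C", "G", "T") else c("R", "Y")
  g <- discretize_gamma(model$alpha, model$ncat)
  # per-site rate class: 0 = invariant, else gamma category
  cls <- sample.int(model$ncat, length, replace = TRUE)
  inv <- stats::runif(length) < model$pinv
  # variable-site rates carry the 1/(1-pinv) rescaling so that `rate` is the
  # expected substitutions/site/My averaged over all sites
  site_rate <- ifelse(inv, 0, g$rates[cls] / (1 - model$pinv))
  tr <- stats::reorder(chron$tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  node_states <- matrix(NA_integer_, nnode, length)
  root <- ntip + 1L
  node_states[root, ] <- sample.int(model$k, length, replace = TRUE,
                                    prob = model$freqs)
  # preorder over edges
  edges <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]
  durs <- chron$ages[edges[, 1]] - chron$ages[edges[, 2]]
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; chd <- edges[e, 2]
    bl <- rate_mult * branch_rates[chd] * durs[e]
    child <- node_states[par, ]
    for (rc in unique(site_rate)) {
      idx <- which(site_rate == rc)
      if (rc == 0) next # invariant sites copy the parent
      P <- transition_probability(model, bl * rc, Q = Q)
      for (st in seq_len(model$k)) {
        ii <- idx[node_states[par, idx] == st]
        if (length(ii))
          child[ii] <- sample.int(model$k, length(ii), replace = TRUE,
                                  prob = P[st, ])
      }
    }
    node_states[chd, ] <- child
  }
  out <- matrix(states[node_states[seq_len(ntip), ]], ntip, length)
  rownames(out) <- tr$tip.label
  out
}

#' Simulate a partitioned alignment along a dated tree
#'
#' Branch rates are drawn once from a mean-1 lognormal with stdev
#' `spec$sigma` and shared across partitions; each partition then evolves
#' under its own model and rate multiplier (substitutions/site/My).  The
#' truth record (tree, branch rates, models) is attached for recovery tests.
#'
#' @param chron an `rm_chronogram`.
#' @param spec an [simulation_spec()].
#' @return an `rm_alignment` with per-column partition labels and attributes
#'   `truth` (list) and `scheme`.
#' @export
simulate_alignment <- function(chron, spec) {
  tr <- stats::reorder(chron$tree, "postorder")
  chron <- list(tree = tr, ages = chron$ages)
  class(chron) <- "rm_chronogram"
  nnode <- length(tr$tip.label) + tr$Nnode
  branch_rates <- with_seed(spec$seed, {
    if (spec$sigma == 0) rep(1, nnode)
    else stats::rlnorm(nnode, meanlog = -spec$sigma^2 / 2, sdlog = spec$sigma)
  })
  blocks <- list(); labs <- character(0)
  for (i in seq_along(spec$partitions)) {
    p <- spec$partitions[[i]]
    nm <- names(spec$partitions)[i]
    blk <- with_seed(spec$seed + 101L * i,
                     evolve_partition(chron, p$model, p$rate, branch_rates,
                                      p$length))
    blocks[[nm]] <- blk
    labs <- c(labs, rep(nm, p$length))
  }
  mat <- do.call(cbind, blocks)
  aln <- alignment(mat, taxa = rownames(mat), labels = labs)
  sc <- scheme_from_labels(labs,
                           encoding = vapply(spec$partitions, function(p)
                             if (p$model$k == 2) "ry" else "nucleotide", ""))
  attr(aln, "scheme") <- sc
  attr(aln, "truth") <- list(chronogram = chron, branch_rates = branch_rates,
                             models = lapply(spec$partitions, `[[`, "model"),
                             rates = vapply(spec$partitions, `[[`, 0, "rate"),
                             sigma = spec$sigma, spec = spec)
  aln
}

# fixture taxa and dated generating tree (ages in My; two deep calibration
# anchors at 11.65 and 20, a radiation near 2.7 and shallow splits < 2)
fixture_newick <- function() {
  asian <- paste0("((Rnor1:0.1,Rnor2:0.1):2.15,((Rexu1:0.3,Rexu2:0.3):1.47,",
                  "(Rrat:0.3,Rtan:0.3):1.47):0.48):0.45")
  ap <- paste0("((((((Rsor:0.49,Rvil:0.49):0.35,Rlut:0.84):0.11,Rtun:0.95)",
               ":0.4,Rfus:1.35):0.2,(Rleu1:0.6,Rleu2:0.6):0.95):0.11,",
               "Rpraet:1.66):1.04")
  sprintf("(Vole:20,(Mouse:11.65,(%s,%s):8.95):8.35);", asian, ap)
}

fixture_models <- function() {
  list(
    codon1 = list(length = 3729L, rate = 0.010,
                  model = gtr_model(c(2, 12, 1.2, 1.5, 14, 1),
                                    c(0.35, 0.27, 0.13, 0.25), 0.40, 0.45)),
    codon2 = list(length = 3729L, rate = 0.004,
                  model = gtr_model(c(2, 10, 1.5, 1.2, 12, 1),
                                    c(0.20, 0.26, 0.13, 0.41), 0.55, 0.40)),
    codon3 = list(length = 3729L, rate = 0.080,
                  model = gtr_model(c(1, 30, 1, 1, 30, 1),
                                    c(0.42, 0.30, 0.05, 0.23), 0.02, 2.0)),
    stem   = list(length = 1600L, rate = 0.006,
                  model = gtr_model(c(2, 10, 1.5, 1.0, 12, 1),
                                    c(0.33, 0.22, 0.18, 0.27), 0.50, 0.35)),
    loop   = list(length = 1684L, rate = 0.015,
                  model = gtr_model(c(2, 10, 1.3, 1.2, 12, 1),
                                    c(0.38, 0.22, 0.12, 0.28), 0.25, 0.50)),
    dloop  = list(length = 578L, rate = 0.200,
                  model = gtr_model(c(1, 15, 1, 1, 15, 1),
                                    c(0.33, 0.26, 0.12, 0.29), 0.05, 0.80)))
}

# interleave the three codon-position partitions into a CDS-like layout so
# that contiguous gene regions contain all three positions
fixture_layout <- function() {
  cds <- rep(c("codon1", "codon2", "codon3"), 3729)
  c(cds, rep("stem", 1600), rep("loop", 1684), rep("dloop", 578))
}

#' Whole-mitogenome-style synthetic fixture
#'
#' A 16-taxon dated tree (two outgroup-side anchor nodes at 11.65 and 20 My,
#' a two-clade radiation below 2.7 My) with a ~15 kb partitioned alignment:
#' an 11,187-column protein-coding block with interleaved codon positions,
#' RNA stem (1600) and loop (1684) blocks, and a hypervariable control-region
#' stand-in (578 columns) that is excluded from the whole-genome column set
#' (mirroring the exclusion of hard-to-align control regions) but provides
#' the third gene region of the short-fragment extraction.  Also bundles the
#' 18-candidate topology set over the fixture taxa.
#'
#' @param seed integer seed; the fixture is deterministic given it.
#' @param dir optional directory: writes the NEXUS alignment with charsets,
#'   the dated truth tree (newick), the truth parameters (TSV) and the
#'   candidate set (multi-newick).
#' @return list with `alignment` (full, labelled), `scheme` (all 6
#'   partitions), `wg_columns` (columns of the whole-genome dataset, i.e.
#'   everything but `dloop`), `wg_scheme`, `regions` (3 [region_spec()]s of
#'   widths 672/702/578), `candidates` (18 topologies, `t1` the generating
#'   one), `truth`, and `spec`.
#' @export
make_wg_fixture <- function(seed = 1L, dir = NULL) {
  layout <- fixture_layout()
  parts <- fixture_models()
  spec <- simulation_spec(n_taxa = 16L, tree = fixture_newick(),
                          partitions = parts, sigma = 0.15, seed = seed)
  chron <- simulate_chronogram(spec)
  aln0 <- simulate_alignment(chron, spec)
  # reorder columns from block layout into the interleaved genome layout
  perm <- integer(length(layout))
  for (nm in names(parts)) {
    src <- which(aln0$labels == nm)
    perm[which(layout == nm)] <- src
  }
  aln <- alignment(aln0$matrix[, perm, drop = FALSE], taxa = aln0$taxa,
                   labels = layout)
  scheme <- scheme_from_labels(layout)
  attr(aln, "truth") <- attr(aln0, "truth")
  wg_columns <- which(layout != "dloop")
  wg_scheme <- subset_scheme(scheme, wg_columns)
  regions <- list(region_spec("cytb", rbind(c(1L, 672L))),
                  region_spec("coi", rbind(c(673L, 1374L))),
                  region_spec("dloop", rbind(c(14472L, 15049L))))
  out <- list(alignment = aln, scheme = scheme, wg_columns = wg_columns,
              wg_scheme = wg_scheme, regions = regions,
              candidates = fixture_candidates(),
              truth = attr(aln0, "truth"), spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_alignment(aln, file.path(dir, "fixture.nxs"), "nexus", scheme)
    ape::write.tree(chron$tree, file.path(dir, "truth_tree.nwk"))
    tp <- data.frame(partition = names(parts),
                     length = vapply(parts, `[[`, 0L, "length"),
                     rate = vapply(parts, `[[`, 0, "rate"),
                     alpha = vapply(parts, function(p) p$model$alpha, 0),
                     pinv = vapply(parts, function(p) p$model$pinv, 0))
    utils::write.table(tp, file.path(dir, "truth_params.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_candidate_topologies(out$candidates, file.path(dir, "candidates.nwk"))
  }
  out
}

#' The 18 candidate topologies over the fixture taxa
#'
#' Alternative resolutions of the seven Australo-Papuan lineages (the deep
#' structure — outgroups, the Asian clade and the two-clade split — is common
#' to all).  `t1` is the generating topology of [make_wg_fixture()].
#'
#' @return named list of 18 `ape::phylo` objects.
#' @export
fixture_candidates <- function() {
  ar <- "((Rnor1,Rnor2),((Rexu1,Rexu2),(Rrat,Rtan)))"
  rl <- "(Rleu1,Rleu2)"
  ap <- c(
    t1  = "((((((Rsor,Rvil),Rlut),Rtun),Rfus),RL),Rpraet)",
    t2  = "((((((Rsor,Rvil),Rlut),Rtun),Rfus),Rpraet),RL)",
    t3  = "(((((Rsor,Rvil),Rlut),Rtun),Rfus),(RL,Rpraet))",
    t4  = "(((((Rsor,Rvil),(Rlut,Rtun)),Rfus),Rpraet),RL)",
    t5  = "((((Rsor,Rvil),(Rtun,Rlut)),Rfus),(RL,Rpraet))",
    t6  = "(((((Rsor,Rvil),Rlut),Rtun),(RL,Rfus)),Rpraet)",
    t7  = "((((((Rsor,Rvil),Rlut),Rtun),RL),Rpraet),Rfus)",
    t8  = "(((((Rsor,Rvil),Rtun),Rlut),(Rfus,Rpraet)),RL)",
    t9  = "((((Rsor,Rvil),Rtun),Rlut),((RL,Rfus),Rpraet))",
    t10 = "(((Rsor,Rvil),(Rtun,Rlut)),((Rfus,Rpraet),RL))",
    t11 = "((((Rsor,Rvil),Rlut),Rtun),((RL,Rfus),Rpraet))",
    t12 = "((Rsor,Rvil),((Rlut,Rtun),(Rfus,(RL,Rpraet))))",
    t13 = "((((Rsor,Rtun),Rvil),(Rlut,Rfus)),(RL,Rpraet))",
    t14 = "(((((Rsor,Rvil),RL),Rfus),(Rtun,Rlut)),Rpraet)",
    t15 = "((((Rsor,Rvil),Rlut),Rtun),(Rfus,(RL,Rpraet)))",
    t16 = "(((((Rsor,Rvil),Rlut),Rtun),(Rpraet,Rfus)),RL)",
    t17 = "((((Rsor,Rlut),Rtun),((Rvil,Rfus),Rpraet)),RL)",
    t18 = "((Rsor,Rvil),((Rlut,Rtun),((Rfus,Rpraet),RL)))")
  out <- lapply(ap, function(x) {
    x <- gsub("RL", rl, x, fixed = TRUE)
    ape::read.tree(text = sprintf("(Vole,(Mouse,(%s,%s)));", ar, x))
  })
  names(out) <- names(ap)
  out
}
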