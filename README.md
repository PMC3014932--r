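# ratmito

Mitogenome phylogenomics and relaxed-clock divergence dating for the
Australo-Papuan radiation of *Rattus*, as one tested R pipeline.

The biological question this toolchain serves: the native rats of Australia
and New Guinea form a clade sister to the Asian *Rattus* species, and the
order and timing of their divergences (roughly 0.5–2.7 Mya) are hard to
resolve because the radiation was rapid and the fast-evolving parts of the
mitochondrial genome are saturated at the relevant depths.  The pipeline
covers every analysis stage that question needs:

* **Alignments and partitions** — FASTA/NEXUS I/O with `charset` blocks
  (stride syntax, interleaved matrices), codon/stem/loop partition schemes,
  RY recoding of saturated positions (`A,G,R → R`; `C,T,Y → Y`; everything
  else missing), gene-region extraction (e.g. a 672+702+578 = 1952-column
  three-gene subset), and non-overlapping genome windows.
* **Likelihood** — Felsenstein-pruning GTR+I+Γ₄ for nucleotide partitions
  and the two-state time-reversible analogue for RY-coded data, partitions
  unlinked, sitewise log-likelihoods exported; branch lengths by per-edge
  line search, model parameters by Nelder–Mead, both in a C++ kernel.
* **Inference** — NNI hill-climbing ML search from an NJ start tree,
  nonparametric bootstrap (within-partition resampling), clade-support
  summaries (BS/BPP node annotations), and a sliding-window bootstrap scan
  of clade support along the genome.
* **Topology tests** — sitewise log-likelihood matrices over a named
  candidate set, RELL resampling, the Kishino–Hasegawa test, and the
  approximately unbiased (AU) test via the multiscale bootstrap with the
  probit-scale curve fit `z(r) = d√r + c/√r`, `p_AU = 1 − Φ(d − c)`.
* **Dating** — Bayesian relaxed-clock MCMC (uncorrelated lognormal branch
  rates), birth–death or constant-size coalescent tree priors, calibration
  priors (normal-from-central-95%, uniform, lognormal-from-median-CI),
  monophyly constraints, ESS/HPD diagnostics, maximum-clade-credibility
  trees with median node heights, and relative-depth age scaling.
* **Synthetic data** — a seeded generator producing dated trees, lognormal
  branch rates, and partitioned alignments; `make_wg_fixture()` emulates a
  16-taxon, ~14.5 kb mitogenome dataset (interleaved codon positions, RNA
  stem/loop blocks, a saturating control-region stand-in) plus the
  18-candidate topology set, so the whole pipeline is verifiable offline.

## Worked example

```r
library(ratmito)

fx  <- make_wg_fixture(seed = 1)          # 16 taxa, 15,049 columns + truth
wg  <- alignment(fx$alignment$matrix[, fx$wg_columns],
                 taxa = fx$alignment$taxa,
                 labels = fx$alignment$labels[fx$wg_columns])
sch <- fx$wg_scheme
wg  <- ry_recode(wg, "codon3", sch); sch$encoding[["codon3"]] <- "ry"

res <- ml_search(wg, sch, seed = 1)
res$loglik
#> [1] -39912.92
ape::dist.topo(res$unrooted, ape::unroot(fx$candidates$t1))
#> [1] 0
```

The search recovers the generating topology (`t1`); the log-likelihood is
the sum over the five unlinked partitions (codon positions 1–2, RY-coded
codon 3, RNA stems and loops).  Candidate-topology testing and dating
continue from the same objects:

```r
sw <- sitewise_matrix(fx$candidates, wg, sch)   # 18 topologies x 14,471 sites
tt <- topology_tests(sw, n_reps = 10000, seed = 1)
head(tt[order(tt$delta), c("topology", "delta", "p_au", "p_kh")])
```

Here `delta` is each topology's log-likelihood distance from the best tree
and `p_au`/`p_kh` are its AU and KH p-values: the generating topology sits
at `delta = 0` with `p_au` near 1 (0.98 at seed 1), and markedly worse
rearrangements are rejected at any conventional level.

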