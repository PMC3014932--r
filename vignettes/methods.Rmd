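---
title: "Models and methods behind ratmito"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ratmito}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ratmito` re-implements, as one tested pipeline, the mitogenome
phylogenomic workflow used to study the Australo-Papuan radiation of
*Rattus*: partitioned maximum-likelihood inference with RY recoding of
saturated sites, candidate-topology testing from sitewise log-likelihoods,
a genome-window clade-support scan, and Bayesian relaxed-clock divergence
dating with fossil calibrations.  This vignette documents the models, the
numerical choices, and what the synthetic data do and do not demonstrate.

## Data model and partitions

An alignment is a taxa-by-columns character matrix over the IUPAC alphabet
plus `-` (gap) and `?` (missing), with optional per-column partition labels.
The canonical whole-mitogenome layout partitions the protein-coding block
into the three codon positions and the RNA genes into stem and loop classes;
the hypervariable control region is carried as a named region but excluded
from the whole-genome likelihood dataset because at deep divergences it is
effectively saturated (and in real data, unalignable).  All user-facing
coordinates are 1-based and inclusive, the NEXUS convention; `charset`
statements with stride syntax (`1-3729\3`) and interleaved matrices are
accepted, and output is always non-interleaved.

RY recoding maps `A`, `G`, `R` to `R` and `C`, `T`, `Y` to `Y`.  Every other
symbol — including all two- and three-state IUPAC ambiguities that mix a
purine and a pyrimidine, `N`, and gaps — becomes missing, because
purine/purine and pyrimidine/pyrimidine ambiguities are the only codes whose
information survives a two-state projection.  Recoding is idempotent and
never touches columns outside the chosen partition.

## Likelihood

Likelihoods are computed by Felsenstein pruning in a small C++ kernel
(per-node rescaling guards underflow in the static-tree entry points).
Nucleotide partitions use GTR with stationary frequencies `pi`, six
exchangeabilities (GT fixed at 1), a proportion `pinv` of invariant sites,
and 4-category discrete-gamma rates; RY partitions use the two-state
time-reversible analogue with free state frequencies.  The rate matrix is
normalized so one unit of branch length is one expected substitution per
site at stationarity.

Two conventions deserve explicit statement:

* **Gamma discretization** uses equal-probability bins with per-bin mean
  rates (median rates available via `method = "median"`), normalized to mean
  1.  Shapes above `1e5` are treated as the homogeneous limit (the
  discretized rates then differ from 1 by less than ~4e-3).
* **Invariant sites** follow the convention of the common ML programs: the
  variable-site category rates are rescaled by `1/(1 - pinv)`, so branch
  lengths count expected substitutions per site averaged over all sites,
  invariant ones included.  The simulator uses the same convention, so
  fitted and generating branch lengths are directly comparable.

Gaps and `?` integrate over all states; IUPAC ambiguities over their state
subsets.  Partitions are unlinked: each gets its own model parameters and
branch lengths, and the total log-likelihood is the exact sum over
partitions (this mirrors workflows in which each partition is run
separately and sitewise log-likelihoods are concatenated afterwards).

Branch lengths are optimized one edge at a time by a golden-section search
on log branch length over `[1e-8, 20]` (tolerance `brent_tol`, default
1e-6), sweeping the tree in preorder with partial-likelihood reuse so each
1-D problem costs roughly one edge's worth of pruning; sweeps repeat until
the gain per pass falls below `tol`.  An accepted step is never worse than
the incoming length, so the log-likelihood is non-decreasing.  Model
parameters are fitted by Nelder-Mead on transformed coordinates
(log exchangeabilities, log shape, logistic `pinv`), alternating with
branch-length sweeps.  Because the joint likelihood in `(alpha, pinv)` has a
long shallow ridge, the first round starts from the best point of a coarse
5x5 grid over that pair; without this the alternation can stall far from
the optimum.  Starting branch lengths are rescaled so the mean root-to-tip
depth matches half the mean pairwise JC distance, which protects the
optimizer when the input tree is on another scale (e.g. a time-calibrated
chronogram).

A practical limitation worth knowing: at single-partition sizes of a few
kilobases the maximum-likelihood `(alpha, pinv)` pair is weakly identified —
the optimum is sharp in likelihood but displaced along the ridge, so the
fitted `alpha` alone can sit 20-30% from its generating value even when the
fit is correct.  Recovery checks of `alpha` therefore condition on the other
generating parameters; the joint fit is validated by its log-likelihood
reaching the global optimum.

## Tree search, bootstrap, and the window scan

The ML search is NNI hill climbing from a neighbor-joining start tree
(JC-corrected distances).  Candidate rearrangements are scored by optimizing
only the central branch of the interchange (all else fixed), the first
improvement in a seeded random edge order is accepted, and all branch
lengths are refitted after each accepted move; the search is deterministic
given its seed.  At the 16-taxon scale of this package NNI is sufficient;
SPR/TBR are out of scope.

Nonparametric bootstrap support resamples columns with replacement — within
partitions when a scheme is supplied — and counts the percentage of
replicate best trees displaying each queried bipartition (clade and
complement are canonicalized to one key, so both receive identical support).
Model parameters are fitted once on the original data and held fixed across
replicates, the usual fast-bootstrap practice.

The genome-window scan cuts the alignment into consecutive non-overlapping
windows (default 1000 columns; the final partial window is analysed and
flagged with its true width rather than discarded), fits an unpartitioned
GTR+I+Gamma model per window, and bootstraps each window.  Because clades
are counted independently, two compatible clades can sum to more than 100%
in the same window.  The default of 100 replicates per window gives 1%
support granularity; tests and the acceptance script use 25-60 replicates,
which is enough to separate a planted conflicting region from sampling
noise.

## Candidate-topology tests

For a named set of candidate topologies, branch lengths are optimized per
partition on each topology (model parameters fixed at values fitted on the
first candidate, or supplied) and the per-partition sitewise log-likelihoods
are concatenated in alignment order; row sums equal the trees' total
log-likelihoods, and the best tree defines `delta = 0`.

RELL resampling draws site indices with replacement and re-sums the stored
sitewise values without re-optimization.  The KH test compares two
topologies by centering the resampled log-likelihood differences and
reporting the one-sided tail probability of the observed difference for the
worse tree.  The AU test runs the multiscale bootstrap at relative sample
sizes 0.5-1.4 (step 0.1, ten scales), transforms each scale's bootstrap
proportion `bp` of a topology being best through the probit, and fits
`z(r) = d*sqrt(r) + c/sqrt(r)` by weighted least squares with the
delta-method weights `B * phi(z)^2 / (bp (1 - bp))`; the reported p-value is
`1 - Phi(d - c)`.  Proportions of exactly 0 or 1 are clamped to `1/(2B)`
before the transform; a topology best in every replicate at every scale is
reported as `p = 1` directly, and one never best anywhere as `1/B`.  The
default is 10,000 replicates per scale; the tests use fewer where the
deltas are large and the decision is insensitive to Monte-Carlo noise.

## Relaxed-clock dating

Dating is Metropolis-Hastings MCMC over node ages, independent per-branch
lognormal rate multipliers (mean 1, stdev `sigma` estimated — the
uncorrelated-lognormal clock realized directly rather than through rate
discretization), per-partition rate multipliers (substitutions/site/My),
substitution parameters, and optionally topology within monophyly
constraints.  Stationary frequencies stay at their empirical values.  The
proposal set is: uniform node-age slides between parent and oldest child;
scale moves on the root age, branch rates, `sigma`, partition rates, shape,
and exchangeabilities; a reflected random walk on `pinv` over `[0, 0.8]`;
constrained narrow exchange for topology; and subtree-scale moves that
multiply all internal ages inside a clade by a common factor (these
decorrelate clade depth from rates and are essential for mixing of deep-node
ages).  All randomness flows from the run's single seed.

Tree priors: a birth-death process conditioned on the number of tips, in the
per-node-age factorized form `sum log(lambda p1(t))` with
`p1(t) = (lambda-mu)^2 e^{-(lambda-mu)t} / (lambda - mu e^{-(lambda-mu)t})^2`
(pure birth when `death = 0`; for two tips the density is properly
normalized over the root age), or a constant-size coalescent.  Calibrations
come in three families — normal specified by its central-95% bounds
(truncated at 0), uniform, and lognormal specified by a median and 95%
interval (the log-scale spread is the least-squares fit to the interval).
Under the birth-death prior a calibrated node's per-node prior factor is
*replaced* by its calibration density, so prior-only marginals of calibrated
nodes reproduce the calibration (up to the genuine joint constraint that
ancestors are older than descendants); under the coalescent, which does not
factorize per node, the calibration multiplies the prior instead.
Calibrated clades are automatically constrained monophyletic, and every
sampled tree satisfies every constraint.

The starting state is a constraint-respecting average-linkage tree rescaled
to the first calibration's central age; partition-rate starting values (and
the center of their diffuse lognormal prior) come from a crude
distance-over-depth estimate.  Burnin defaults to 10% of samples in the
summaries, with the full trace always returned for inspection (effective
sample sizes use Geyer's initial-positive-sequence truncation).  The MCC
summary picks the sampled topology maximizing the product of clade
posterior probabilities and sets node heights to each clade's median
sampled age with 95% HPD intervals (shortest-interval definition); as with
the standard tree annotators, a median-height tree can in principle place a
node older than its parent, which is reported as-is.

A preset worth noting: the constrained short-fragment analysis removes the
outgroup effect by constraining the two major clades and placing a
lognormal prior on the root derived from a previous run's posterior
(`calibration_from_samples()`), mirroring how a saturation-affected
short-fragment dataset can be anchored by a whole-genome result.

## The synthetic-data generator

`make_wg_fixture()` emulates the statistical structure of the
whole-mitogenome study dataset: 16 taxa on a fixed dated tree with two deep
anchor nodes (11.65 and 20 My) and a two-clade radiation below 2.7 My; an
11,187-column protein-coding block with interleaved codon positions, RNA
stem (1600) and loop (1684) blocks, and a 578-column hypervariable
control-region stand-in that is excluded from the 14,471-column whole-genome
dataset but supplies the third gene region of the 672+702+578 = 1952-column
short-fragment extraction.  Branch rates are drawn once per tree from a
mean-1 lognormal with stdev 0.15 and shared across partitions; partitions
then evolve independently under their own GTR+I+Gamma models and rate
multipliers (0.004-0.08 substitutions/site/My for codon and RNA classes,
0.2 for the control region — chosen to reproduce rodent-mitogenome rate
contrasts and deep-branch saturation of the fast classes).  The
control-region stand-in is an ordinary high-rate GTR+I+Gamma partition, not
a bespoke hypermutation model: only its saturation behaviour matters
downstream.  No indels are simulated; alignment estimation is out of scope.
Seeds propagate hierarchically (tree, branch rates, then one stream per
partition), so partitions can be regenerated independently, and the 18
candidate topologies over the fixture taxa (alternative resolutions of the
seven ingroup lineages; `t1` generates the data) ship with the bundle.

What passing tests show — and do not show.  The generator matches the
analysis assumptions exactly (no alignment error, no recombination, no
compositional non-stationarity, clock rates truly lognormal), so recovery
tests validate the *implementation*, not the robustness of the method to
real-data violations.  One violation is deliberately built in: the
control-region stand-in saturates at deep divergences, and analyses that
include it reproduce the classic symptom of inflated deep divergence dates,
which is why the dating recovery checks run on the saturation-free subset
while the saturated behaviour is exercised by the scan and topology-test
stages.

## Problem sizes used by the tests

The test-suite and acceptance-script problem sizes are the package's
desk-scale study conditions: the full 14.5 kb fixture for ML search and the
18-topology tests (20 seeds for the AU coverage check), 200 null
simulations with reduced RELL replicates for the KH type-I check, 2 kb
saturation-free subsets with 200,000-state chains and 20 replicates for the
dating coverage check, 2,000,000-state prior-only chains for the
calibration-sampling check, and 4-5 kb, 8-taxon mosaics for the window-scan
checks.  These sizes were chosen so each stage's statistical target (e.g.
>= 90% HPD coverage) is measurable with modest Monte-Carlo error.

## Known limitations

* NNI-only search; no SPR/TBR (adequate at 16 taxa, not for the 126-taxon
  short-fragment dataset, whose generic machinery is supported but whose
  full-scale analysis is not a test target).
* The MCMC kernel skips partial-likelihood rescaling and is intended for
  trees up to a few dozen taxa.
* `alpha`/`pinv` are jointly weakly identified at few-kilobase partition
  sizes (see above).
* Metropolis coupling is not implemented; the desk-scale targets mix
  adequately unheated, with the subtree-scale move doing the heavy lifting.
* The birth-death prior's calibrated-node replacement is exact only for
  priors that factorize over node ages; the coalescent path multiplies
  calibration and prior, and its prior-only marginals therefore shift where
  the two conflict.
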