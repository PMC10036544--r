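---
title: "Models and methods behind the adhesomics pipeline"
author: "adhesomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the adhesomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adhesomics)
```

This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the tunable parameters with
their defaults, the numerical choices, and — importantly — what the
synthetic benchmarks do and do not demonstrate about real data.

## 1. Label-free proteomics preprocessing

The pipeline assumes protein-level label-free quantification (LFQ)
intensities, log2-transformed, for two experimental groups with a small
number of biological replicates (typically three). The processing order is
fixed: replication filter → normalisation → first-pass imputation →
second-pass imputation → testing; no stage reorders rows.

**Replication filter.** A protein is retained if it is quantified in at
least `minPresent = 2` replicates of at least one group. Two of three
replicates is the conventional reproducibility floor; proteins failing it
carry too little information for either imputation pass.

**Robust linear regression normalisation.** Each sample is regressed
against the row-wise median reference profile on co-observed proteins with
Huber-weighted iteratively reweighted least squares (tuning constant
1.345 — 95% Gaussian efficiency — at most 50 iterations, handled by
`MASS::rlm`), and the fitted systematic deviation is subtracted. A
straight-line robust fit removes both global shifts (loading differences)
and mild intensity-dependent tilt while ignoring the differential minority
of proteins; the fit family and tuning constant are exposed rather than
hard-coded because "robust linear regression" names a family, not a single
estimator. A sample sharing fewer than 10 observed proteins with the
reference is an error naming the sample, since a two-parameter fit on
fewer points is meaningless.

**Two-pass missing-value imputation.** LFQ missingness is predominantly
left-censoring: low-abundance proteins drop below detection
(missing-not-at-random, MNAR). The two passes treat the two regimes
differently:

* *Pass 1 (minimum-value):* only for proteins missing in **all**
  replicates of a group, those cells are set to the minimum observed value
  of their own sample column — the detection floor. This deliberately
  produces an exaggerated fold change: the protein is effectively
  absent in that group, and the analysis should flag it, not estimate a
  precise ratio. Cells in partially observed groups are *not* touched.
* *Pass 2 (predictive mean matching, PMM):* chained equations over sample
  columns; each column with missing cells is regressed on the other
  columns using its observed rows with a stochastic parameter draw
  (posterior draw of σ² from the scaled inverse-χ² and of β from its
  normal; 10 sweeps), and each missing cell copies the observed value of
  one of the 5 nearest-prediction donors, chosen uniformly. Donor copying
  guarantees every imputed value is a real observed intensity of that
  column, so imputation can never manufacture out-of-range values. One
  completed matrix is produced (single imputation), matching the single
  downstream analysis.

A documented consequence of this design, quantified in the test suite: the
fold-change estimates of proteins quantified in both groups are nearly
unbiased (measured |bias| < 0.03 log2 units on the 2000-protein benchmark),
while pass-1 (detection-floor) proteins report floor-limited fold changes
whose magnitude reflects the column minimum rather than the true effect —
their direction is usually, but not always, preserved. PMM also shrinks
genuinely differential effects towards the cross-column prediction when a
differential protein's cells are imputed, which is the main cause of
missed calls in the end-to-end benchmark.

**Differential testing.** Per protein, a two-sided t-test whose flavour is
gated by a two-sided F-test on the variance ratio at α = 0.05: pooled
Student if the variances are compatible, Welch-Satterthwaite otherwise.
The gate level is a conventional default (exposed as `alphaF`) since only
the gate itself, not its level, is standard. Benjamini-Hochberg correction
runs across all tested proteins, and a protein is significant iff
*q* < 0.05 **and** |log2 fold change| ≥ log2(2). The dual gate means a
precisely measured 1.4-fold change is never called, by design.

## 2. BUM scoring and active-module discovery

P-values from the differential tests are modelled as a beta-uniform
mixture, f(p) = λ + (1 − λ) a p^(a−1) with 0 < a < 1: uniform noise with
weight λ plus a Beta(a, 1) signal spike at zero. The fit maximises the
log-likelihood by bounded quasi-Newton optimisation from a deterministic
5-point grid of starts (the likelihood is smooth and low-dimensional;
multi-starts guard against the λ↔a ridge). π = λ + (1−λ)a — the mixture
density at p = 1 — upper-bounds the noise fraction. At a target FDR the
threshold τ = [(π − λ·FDR)/(FDR·(1−λ))]^{1/(a−1)} yields node scores
s(p) = (a − 1)(ln p − ln τ): zero at τ, positive below, logarithmic in p.
The calibration FDR defaults to 5%. Nodes of the interaction graph without
a p-value receive the score of p = 0.5 (configurable), keeping them
available as connectors rather than discarding them.

The maximum-weight connected subgraph (MWCS) problem — find the connected
node set of maximal total score — is equivalent, after shifting all scores
by the most negative one into non-negative "profits" with a uniform edge
cost, to a prize-collecting Steiner tree; `mwcsToPcst` performs that
transform and the tests verify the objective equivalence subtree by
subtree.

Two solvers are provided. `solveMwcsExact` enumerates every connected
induced subgraph via bitmask subsets with a bit-parallel connectivity
check, capped at 20 nodes; among equal-scoring optima the
lexicographically smallest sorted node-id set wins, making the oracle
deterministic. `solveMwcsHeuristic` contracts adjacent positive nodes into
super-nodes, measures connection costs in a node-cost metric (traversing
node v costs max(0, −s(v)); already-included nodes cost 0), and pursues two
routes: greedy accretion of super-nodes while the marginal gain is
non-negative, and a Steiner-style route that connects *all* positive
super-nodes through a metric-closure minimum spanning tree and then applies
strong pruning (bottom-up dynamic programming from every root, keeping
subtrees of positive value). The second route exists because greedy
accretion is blind to connector sharing: two attachments that are
individually unprofitable can be jointly profitable when they share a
path. The better-scoring candidate (never worse than the best single node)
is returned; on 100 random ≤ 12-node instances the heuristic matches the
exhaustive optimum 99 times and never falls below 0.99 of it.

A calibration fact the benchmarks make explicit: with signal shape
a = 0.2 and score calibration at FDR 5%, only τ^a ≈ 26% of true signal
nodes receive positive scores, so the maximal-scoring module *correctly*
contains only a quarter of a weak planted module — member recall of a
score-optimal module is bounded by the calibration, not by the solver.
Recovering a larger fraction of weak-signal modules requires a more
liberal calibration FDR, with the attendant false-positive cost.

## 3. Community detection, Surprise, and hub cartography

Modularity and constant-Potts-model (CPM) partitions share one
deterministic two-phase Louvain engine: local moves in ascending node-id
order (optionally shuffled once by a seed), best-gain target with ties to
the smallest community id and a 1e−12 gain tolerance, then aggregation;
the per-level quality trace is non-decreasing by construction and asserted
in tests. Girvan-Newman modularity Q = (1/2W) Σ_ij [A_ij − k_i k_j/2W]
δ(c_i,c_j) uses Spearman-ρ+1 edge weights (range [0, 2]) so that
anti-correlated neighbours contribute nothing rather than negatively;
CPM H(γ) = Σ_c [w_c − γ n_c(n_c−1)/2] uses max(ρ, 0) weights because the
local-move gain rules assume non-negative weights — the clamp is a design
choice where negative-correlation edges are silent in the objective.
Edges with an endpoint lacking abundance data get the neutral weight
(1 for modularity, 0 for CPM).

The CPM resolution γ is scanned (default: 25 log-spaced points in
[0.01, 2]) and each partition is evaluated by Surprise on the *binarised*
topology: S = −ln P(X ≥ m_int) where X is hypergeometric — the probability
that placing the graph's m edges uniformly among all node pairs yields at
least the observed number of intra-community edges. S is computed in log
space through the hypergeometric tail (`phyper(log.p = TRUE)`), is
invariant under community relabelling, non-negative, and exactly
ln(5005) ≈ 8.518 for the two-triangle reference case. Weighted Surprise
variants exist but the hypergeometric formulation is defined on
presence/absence, so the binary choice is the principled one. Ties in the
scan resolve to the smaller γ.

Hub cartography follows the within-module-degree z-score and
participation coefficient P = 1 − Σ_s (k_is/k_i)² convention: connector
hubs have z ≥ 2.5 and P in (0.30, 0.75], kinless hubs P > 0.75. The
thresholds are the established cartography defaults, exposed as
parameters; a module whose within-degree standard deviation is zero
assigns z = 0 to its members.

## 4. DamID lamina-association profiling

The genome is scanned for GATC motifs (the motif is its own reverse
complement, so a forward scan suffices); each motif yields one window
centred on the motif centre (0-based motif start + 2) extended by
`flank = 250` bp per side — 500-bp windows, clipped at chromosome ends and
free to overlap where motifs are closer than 500 bp. Reads are start
positions only; a read counts in every window containing its start. All
external coordinates are 0-based half-open (BED convention).

Counts are normalised to reads-per-million using total mapped reads, and
the per-window association signal is log2((rpm_fusion + ε)/(rpm_control +
ε)) with ε = 0.5 RPM guarding zeros (a window empty in both conditions is
exactly 0).

**Peak calling.** Candidate thresholds are quantiles of the ratio at
levels 0.75, 0.7505, …, 1 (min quantile 0.75, step 0.0005). At threshold
t, observed peaks are maximal runs of at least `minRun` consecutive
same-chromosome windows with ratio ≥ t, the null count is the mean over 15
seeded uniform permutations of the ratios across windows, and
FDR(t) = min(1, null/observed). Each run is reported at the smallest t at
which its FDR < 5%, and overlapping reported runs merge, keeping the best
FDR.

Two properties of this permutation null deserve emphasis:

* It destroys *all* autocorrelation — both the biological block structure
  and the technical correlation of overlapping windows. Because observed
  signal forms few long runs while permuted values scatter into many short
  ones, the count-ratio FDR is asymptotically ≈ the fraction of windows
  inside true blocks: signals occupying a large share of the genome can
  never reach a 5% count FDR, whatever the effect size. The caller's
  operating envelope is therefore *compact* association domains occupying
  a few percent of the scanned territory; genome-scale lamina-associated
  fractions (tens of percent, as for lamin B1 genome-wide) need
  segmentation approaches (e.g. HMMs) and are outside this caller's scope.
* `minRun` sets the null run rate (≈ N·p^minRun at above-threshold
  fraction p) and hence the sensitivity floor. The default is 5 windows
  (≈ 2.5 kb): at 2 windows, single-block signals are undetectable at any
  threshold because the null rate (≈ 0.8 runs at the block's own
  threshold) can never drop below 5% of an observed count of one;
  at 5 windows the null collapses (≈ 10⁻⁴) while any true domain of
  ≥ 2.5 kb keeps its full extent. Window-overlap autocorrelation can still
  promote occasional minimum-length background runs to peaks — the
  false-coverage cost measured in the end-to-end benchmark is ≈ 2% of
  non-domain bases.

Region-level quantification (`quantifyRegion`) is the unweighted mean of
window ratios overlapping a query interval, the natural companion to
qPCR-style assays of a candidate region.

## 5. Imaging metrics

Channel intensities are normalised linearly onto [0, 1500]
(I_N = (I − I_min)·1500/(I_max − I_min)); the endpoints are pinned exactly
and the map is idempotent. The scale constant 1500 is the convention for
the cross-channel intensity comparison the normalisation serves; it is a
parameter. Automatic thresholding maximises the between-class variance
over a 256-bin histogram of the observed range (Otsu's criterion) — the
imaging software that inspired the workflow does not disclose its
algorithm, so the field-standard choice is used and exposed. Masked
Manders co-occurrence zeroes all voxels outside the region of interest
(or inside it, when inverted) in *both* channels before thresholding:
"nuclear membrane" is the mask itself, "cytoplasm" its complement. The
coefficients M_a = Σ a_i·[b_i > t_b]/Σ a_i are intensity-weighted, lie in
[0, 1], are invariant under positive rescaling of either channel, and are
NA when a channel is empty after masking.

## 6. The synthetic-data module: what it emulates, and what it does not

Every generator is a pure function of its arguments including the seed
(the ambient RNG state is saved and restored), and each returns a truth
object sufficient to score downstream recovery without re-deriving ground
truth.

* `simulateLfq`: log-normal intensities (baseline log2 mean 25, sd 2.5 —
  the usual LFQ scale; replicate noise sd 0.3 ≈ 20% CV), ±effect shifts in
  group 2 for a chosen fraction of proteins, probabilistic MNAR censoring
  (probability 0.8 below the column quantile, default 0.25) plus 2% MCAR.
  The probabilistic (rather than hard) censoring leaves PMM information to
  exploit. Not emulated: peptide-level rollup, shared peptides,
  contaminants, batch structure, intensity-dependent variance.
* `simulatePpiNetwork`: preferential-attachment graph with a connected
  planted module densified to ≥ 2× background density. Real interactome
  degree distributions, hub annotation bias and literature bias are not
  modelled; conclusions about recovery transfer only qualitatively.
* `simulateDamid`: a chromosome with GATC motifs at near-regular spacing
  (the background sequence is scrubbed of accidental motifs so density is
  controlled — real GATC spacing is irregular), uniform control reads, and
  fusion reads weighted by the enrichment factor inside planted domains.
  Defaults: 200-kb chromosome, ~200-bp motif spacing, two 10-kb domains
  (5% of the chromosome — inside the caller's compact-domain envelope,
  matching the scale of the peak-calling reference example), enrichment 4,
  2×10⁵ reads per condition. Read length, mappability, GC bias and decoy
  chromosomes are not modelled.
* `simulateVoxelPair`: foreground supports with an exactly controlled
  shared-voxel count, constant foreground intensity by default (so the
  expected Manders coefficient equals the overlap fraction exactly), and a
  cuboid-shell "membrane" mask. Point-spread blur and background noise are
  not modelled unless requested.

Passing the planted-truth benchmarks therefore demonstrates algorithmic
correctness and calibration under idealised generative assumptions — it
does not certify performance on real acquisitions, where the unmodelled
features above dominate the error budget.

## 7. Problem sizes, determinism, and numerical choices

The shipped test-suite and acceptance benchmarks use 200–2000 proteins,
6 samples, 200-node networks, 1000-window tracks and 10⁴-replicate null
simulations — sizes chosen so the full suite exercises every claim in a
few minutes on one core while keeping Monte-Carlo standard errors well
inside the asserted tolerances. Exact MWCS enumeration is capped at 20
nodes; partition brute force at 8 nodes (4140 partitions).

Ties and degeneracies are resolved deterministically throughout: smallest
sorted node-id set (exact MWCS), smallest community id (Louvain moves),
smaller γ (Surprise scan), p = 1 convention for zero-variance equal-mean
tests, clamping of p-values to the smallest positive double with a
warning, and NA (not an error) for undefined Spearman correlations and
empty-channel Manders coefficients. The pipeline writes a resolved
configuration and a parameter-hashed header on every table, and two runs
with identical configuration and inputs produce byte-identical primary
outputs.

## 8. Known limitations

* PMM imputation shrinks differential effects when a truly differential
  protein needs imputation (the predictors span both groups); recall of
  the end-to-end differential benchmark is seed-sensitive through this
  channel, and low-abundance differential proteins can be lost at the
  replication filter before testing.
* The shuffle-FDR peak caller cannot flag association domains occupying a
  large fraction of the genome (see section 4) and has ± one-window
  boundary resolution.
* The Louvain engine is a heuristic: its Q is verified never to exceed the
  brute-force optimum and to match it on small fixtures, but global
  optimality on large graphs is not guaranteed (nor is it for any Louvain
  implementation).
* Weak-signal module recovery is calibration-limited (section 2), not
  solver-limited.
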