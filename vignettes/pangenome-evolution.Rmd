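---
title: "Models and methods behind pangloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pangloss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangloss)
options(pangloss.quiet = TRUE)
```

pangloss implements the computational core of a bacterial
pangenome-evolution study: how open a species' gene pool is, how genomes
cluster by identity and gene content, which genes drive that structure,
which genes look horizontally acquired, where in the phylogeny gene
families were gained and lost, and which community members co-occur with
a focal species across metagenomes.  This vignette explains each model,
the tunable parameters, the numerical choices, and what the simulators
do and do not emulate.

## Pangenome openness

A gene presence/absence matrix (genomes × gene families, as produced by
orthology clustering tools such as Roary) is partitioned by prevalence:
core ≥ 99%, soft-core ≥ 95%, shell ≥ 15%, cloud < 15%.  Prevalences are
integer column sums divided by the genome count, so boundary families
(exactly 99%, 95%, 15%) classify deterministically into the upper set.
The 15% shell/cloud boundary follows the field's convention for "rare"
accessory genes; all three thresholds are arguments.

Openness is assessed by Heaps' law on the *new-genes* curve.  For 1,000
random genome orders (`accumulation_curves()`, the inner scan in C++),
we record the number of novel families contributed at each addition
step, average across permutations, and fit

\[ n_\text{new}(N) = \kappa N^{-\alpha} \]

by ordinary least squares of \(\log n_\text{new}\) on \(\log N\)
(`fit_heaps()`).  The first point is excluded — the first genome
contributes its whole complement, which is not a discovery-law point —
as are zero values, where the logarithm is undefined.  The pangenome is
called *closed* iff \(\alpha > 1\) (Tettelin convention): past that
decay rate the expected total gene pool converges.  A fit needs at
least three usable points.  Note that when the true decay exponent is
exactly 1 the verdict is a coin flip by construction; the verdict is
meaningful only away from the boundary.

**Simulator.** `simulate_pangenome()` must control the *expectation* of
the permutation-averaged curve, because that is what the fit consumes.
Under random genome orders that expectation depends on the data only
through the prevalence spectrum of the families: a family carried by
$k$ of $G$ genomes is first discovered at step $N$ with probability
\(\binom{G-k}{N-1}/\binom{G}{N-1} - \binom{G-k}{N}/\binom{G}{N}\).
The simulator therefore solves a non-negative least-squares problem for
the mixture over $k$ whose exact expected new-gene curve is
\(\propto N^{-\alpha}\), samples each family's prevalence from that
mixture, and assigns it to a uniformly random $k$-subset of genomes.
Genomes are exchangeable by construction, so Monte-Carlo permutation
averages converge to the designed curve.  We verified recovery at
\(\alpha \in \{0.6, 1.0, 1.5\}\) with 200 genomes, a 2,000-family
accessory pool and 1,000 permutations: fitted exponents stay within
±0.15 of truth (typically ±0.05), and the open/closed verdict is stable
away from \(\alpha = 1\).  Sequential-generation schemes we prototyped
(novel families per genome drawn Poisson with a decaying mean, plus
re-draws of used families) biased the fitted exponent upward by
0.25–0.35, precisely because the induced prevalence spectrum, not the
generation order, determines the permuted curve.

What the simulator does not emulate: linkage between families (real
accessory genes travel in islands), genome-size variation, and
annotation noise.  Passing recovery tests therefore show the estimator
is correct for independent families, not that real islands cannot bias
a fit.

## Genome clustering, ordination, and gene influence

Two distances are supported: `1 − gANI` from a square identity matrix
(percent inputs are normalised to fractions; distances are used as-is,
with no re-standardisation) and binary Jaccard distances from the
presence/absence matrix.  `hca_cluster()` performs group-average (UPGMA)
agglomeration; for each candidate $k$ the tree is cut and the
intra-cluster sum of squares computed against the cluster *medoid*,
because only distances — not coordinates — are guaranteed to exist.
`choose_k_elbow()` picks the interior $k$ maximising the perpendicular
distance to the chord of the WCSS curve, breaking ties toward smaller
$k$ (so an exactly linear curve yields $k = 2$).

`pcoa()` is classical scaling (double-centred \(-d^2/2\),
eigendecomposition, eigenvectors scaled by the square root of their
eigenvalues).  Negative eigenvalues — expected for non-Euclidean inputs
such as Jaccard — are dropped from the variance-explained denominator
and logged.  Three axes are examined by default.

Per-gene influence on the ordination (`gene_influence()`) is a
permutation test: for each variable family and axis, the statistic is
the difference in mean axis coordinate between carrier and non-carrier
genomes; the null shuffles the family's presence labels; the z-score
standardises the observed statistic against the null, with a two-sided
normal p-value and Benjamini–Hochberg correction across all
family × axis tests (families significant on any axis are flagged).
Because a permutation's first $k$ entries form a uniform $k$-subset,
one pool of permuted cumulative sums serves every family exactly,
reducing the cost from genes × permutations × genomes to
(genes + permutations) × genomes.  Under a null in which families are
assigned independently of the ordination, the p-values are uniform and
the realised false-discovery proportion at FDR 0.05 stays at the
nominal level (checked over 50 seeds in the test suite).

Cluster–metadata enrichment uses one-vs-rest 2×2 Fisher exact tests per
(cluster, region) pair, BH-corrected, with the dual significance
threshold `p < 1e-5 AND FDR < 0.05` used throughout the pipeline.

## The four-factor screen for horizontally transferred genes

For every codon-clean CDS of a genome, `codon_metrics()` computes:

* **RSCU** — observed codon count × family size / family total, per
  synonymous family; stop codons and the single-codon families (Met,
  Trp) never enter.  The screen thresholds a scalar, so the per-gene
  summary is `rscu_deviation`: the mean absolute difference between the
  gene's RSCU vector and the genome-average RSCU (pooled counts), over
  codons whose family the gene observes.
* **ENC** — Wright's effective number of codons,
  \(2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6\) with
  \(F = (n\sum p^2 - 1)/(n-1)\) per family; families with \(n < 2\) or
  undefined \(F\) are excluded, a missing three-fold mean is imputed as
  \((\bar F_2 + \bar F_4)/2\) (and a wholly absent other class from the
  mean of the available classes), and the result is capped to
  \([20, 61]\).  A gene using each degenerate codon equally often caps
  at 61; a gene using one codon per family scores exactly 20.
* **CAI** — the count-weighted geometric mean of relative adaptiveness
  \(w_c = \mathrm{RSCU}^{ref}_c / \max_\text{family} \mathrm{RSCU}^{ref}\)
  against a highly expressed reference set: genes annotated
  "ribosomal protein", falling back to the 5% of genes with lowest ENC
  when fewer than 20 exist, always overridable.  Reference counts get a
  +0.5 pseudocount.
* **GC** — the G+C fraction of the CDS.

Thresholds are per-genome and dynamic: the nearest-rank 90th percentile
for GC, RSCU deviation and ENC, and the 10th for CAI, computed from at
least 50 genes.  `call_hchtg()` flags a gene per factor when it falls in
the corresponding extreme decile; a gene with all four flags is a
high-confidence horizontally transferred gene (hcHTG).  With
nearest-rank thresholds each factor flags ~10% of genes by
construction, so the hcHTG rate is bounded by 10% and concentrates far
lower when factors are independent.  The default `raw_tail` mode takes
the literal upper tails (so only compositionally *GC-richer* aliens can
flag on GC); `abs_deviation` mode thresholds |GC − median| instead,
catching departures in either direction.  `mobile_context()` marks
genes with a transposase-annotated neighbour within 2,000 nt on the
same contig (nearest-boundary gap, overlap = 0, window-inclusive).

**Simulator.** `simulate_cds()` draws native genes from one genome-wide
codon preference and aliens from an independent preference at a
different GC and bias strength.  Within each synonymous family the
preferred codon receives weight \(1/n + b(1 - 1/n)\) and the rest share
the remainder, all tilted by \(\exp(\eta \cdot \mathrm{GC}_c)\) with
\(\eta\) solved (uniroot on the closed-form expectation) so the
expected gene GC hits the target — the tilt is what decouples the GC
knob from the bias knob.  Defaults (950 native + 50 alien, GC 0.45 vs
0.55, bias 0.6 vs 0.1, 300-codon genes) give the screen ≥ 80%
sensitivity at ≤ 5% native flag rate across seeds.  The simulator does
not emulate amino-acid composition differences, expression-correlated
bias gradients, or ameliorated (old) transfers, whose signal decays
toward the host background — sensitivity on real genomes is
correspondingly lower for ancient acquisitions.

## Gain and loss on the phylogeny

`wagner_events()` reconstructs each family's history on a rooted tree
by Sankoff dynamic programming over the two states with asymmetric
costs: gain (0→1) costs 2, loss (1→0) costs 1 by default.  Presence at
the root is charged one additional gain (a virtual origin from
absence).  Without that convention the cheap loss would make any two
sister carriers "ancestrally present", inflating losses; with it, the
gain penalty acts on origins too.  It can be disabled
(`root_origin = FALSE`).  Among co-optimal reconstructions the
traceback is deterministic: minimise (cost, gains) lexicographically,
then prefer absence.  On the quartet ((A,B),(C,D)) with presence in
{A, C}, both resolutions cost 4; the tie-break selects the present root
with losses on B and D (one origin gain) over two independent gains.
The Sankoff minimum equals exhaustive enumeration over all internal
assignments on hundreds of random trees in the test suite, and with
equal costs and no origin charge it reproduces Fitch parsimony counts.
`pangenome_events()` vectorises the DP across families and memoises
identical presence patterns.

Significance (`event_significance()`) is artifact-defined: the null
shuffles a family's tip states across tips, preserving prevalence while
destroying phylogenetic structure; each tail gets a z-score and a
two-sided empirical p-value with +1 smoothing, BH-corrected across
families.  A GoF/LoF class additionally requires the observed count to
*exceed* the null (z > 0): clustered families have fewer events than
shuffled labels, and that is conservation, not gain/loss signal.  The
dual threshold `p < 1e-5 AND FDR < 0.05` is attainable only with ≥ 1e5
permutations; below that the p-threshold falls back to the smallest
attainable value, with a logged note.  Stability is the fraction of
tip-subsample rounds (default 80% of tips, induced subtree) reproducing
the class.  `classify_lineage_events()` layers the cross-species view:
a family in the focal soft-core but below cloud prevalence in every
sibling species is a lineage gain candidate; a focal-cloud family
conserved (≥ 90%) in some sibling is a lineage loss candidate.

`simulate_gene_histories()` evolves each family by a two-state
continuous-time Markov chain along the branches from a Bernoulli root,
recording true per-branch events.  At low rates (≤ 1 expected event per
family) the reconstruction recovers ≥ 90% of true single-event
branches.  The simulator does not model rate variation across families
or branches, nor horizontal re-acquisition of the same family, both of
which degrade parsimony on real data.

## Co-occurrence networks

`spearman_network()` correlates focal taxa against all partners with
prevalence ≥ 5% (configurable): Spearman rho with average ranks — zeros
are genuine observations and enter the ranking — and p-values from the
large-sample t approximation (the exact tie-free null is used below
n = 12, though strata under 20 samples are skipped anyway).  BH runs
within each (focal, stratum) family; significance uses the dual
threshold; with strata the analysis runs pooled and per region, and
each pooled-significant pair is annotated with the strata in which it
is independently significant.  `taxon_summaries()` reports mean/SD
abundance (zeros included) and prevalence, overall and per stratum.

**Simulator.** `simulate_abundance()` uses a latent Gaussian copula:
planted-positive partners share latent correlation \(+s\) with the
focal taxon, planted-negative \(-s\) (single-factor construction, so
the latent covariance is always positive definite).  Marginals are
log-normal; zero inflation *censors* each taxon below its own absence
quantile — a monotone operation, so planted rank associations survive
as ties at zero and the planted \(s\) remains interpretable on the
Spearman scale.  Abundances are expressed in percent of a *fixed*
community size (expected profiled total × (1 + `unclassified_weight`),
default 9× — profiled species are a minority of a real community).
The fixed denominator matters: dividing by per-sample totals (or any
per-sample random denominator) injects a shared scale factor that
correlates all taxa and inflates the null false-positive rate from 5%
to 7–8%; a global constant is a monotone per-taxon transform and
provably leaves every rank statistic untouched.  The cost is that the
simulator does not reproduce compositional closure effects present in
real relative-abundance data — analyses of real profiles should bear
that in mind; the package tests the *statistic*, not a
compositionality correction.

## Numerical and interface conventions

* Coordinates are 1-based inclusive (GFF3); feature gaps are
  nearest-boundary nucleotide distances with overlap = 0.
* Roary CSV cells binarise on non-emptiness (paralog cells count once);
  the Rtab dialect is read verbatim and round-trips bit-identically.
* Trees must be rooted; missing branch lengths default to 1 (logged).
* All stochastic functions take explicit seeds; identical parameters
  and seed give bit-identical outputs.
* Report writers prefix TSVs with `#` comment lines recording the
  package version, seed and parameters.
* The workflow under `analysis/` (scripts 01–06) regenerates every
  input from the simulators and runs each stage end to end at desk
  scale: 200 genomes × 2,100 families for the openness analysis, 60
  genomes for clustering, one 1,015-gene genome for the HGT screen, a
  64-tip tree × 500 families for parsimony, and 500 samples × 200 taxa
  for the network.  These sizes were chosen so the whole workflow runs
  in a few minutes while leaving each estimator comfortably inside its
  validated operating range.

## Known limitations

* The Heaps fit weights all usable points equally on the log scale;
  late points (few new genes) are noisier and saturated collections
  shorten the usable range.
* The influence statistic assumes the coordinate means are a meaningful
  contrast; heavily imbalanced families (prevalence near 0 or 1) have
  unstable nulls and are skipped only when exactly constant.
* Wagner parsimony with a fixed gain:loss ratio of 2:1 is a modelling
  choice, not an estimate; rate heterogeneity or within-species HGT
  violates it silently.
* The label-shuffling null conditions on prevalence only; families can
  exceed it only by being *anti*-clustered (repeated independent
  acquisition), which is exactly the HGT signature the class is meant
  to capture, but it will not flag single clade-confined acquisitions.
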