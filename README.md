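# pangloss

Pangenome openness, gene gain/loss and co-occurrence analysis for
bacterial genome collections.

Comparative genomics of a bacterial species asks a connected set of
questions: is the species' gene pool still growing as genomes are added
(an *open* pangenome) or has it saturated (*closed*)?  How do genomes
cluster by nucleotide identity and by accessory gene content, and which
gene families drive that structure?  Which genes look horizontally
acquired from their codon usage and GC content?  Where on the phylogeny
were gene families gained and lost?  And with which other community
members does the species co-occur across metagenomes?  pangloss
implements each of these stages as tested, reusable R functions, plus
simulators that generate every input with known ground truth so the
whole pipeline is verifiable without any external data.

## Methods at a glance

* **Openness** — gene accumulation over 1,000 random genome-addition
  orders; the mean new-genes curve is fit by OLS on the log scale to
  Heaps' law `n_new(N) = κ·N^(−α)`; closed iff `α > 1`.  Partition by
  prevalence: core ≥ 99%, soft-core ≥ 95%, shell ≥ 15%, cloud < 15%.
* **Clustering** — `1 − gANI` or binary Jaccard distances; UPGMA with
  elbow-method selection of k on the intra-cluster sum of squares;
  classical PCoA; a permutation z-test for per-gene influence on the
  ordination (BH-corrected); Fisher-exact cluster–metadata enrichment.
* **HGT screen** — per-gene RSCU deviation, Wright's ENC, CAI against a
  ribosomal-protein reference, and GC; per-genome nearest-rank
  percentile thresholds (90th, 10th for CAI); genes extreme in all four
  factors are high-confidence horizontally transferred genes (hcHTGs),
  annotated for transposases within 2,000 nt.
* **Gain/loss** — binary Sankoff/Wagner parsimony with gain cost 2,
  loss cost 1, a root-origin charge, deterministic tie-breaks;
  label-permutation significance with subsample stability; lineage-level
  gain/loss candidates against sibling-species prevalences.
* **Co-occurrence** — Spearman correlations (zero-aware average ranks)
  of focal taxa against all partners, BH FDR within each
  (focal, stratum) family, dual threshold `p < 1e-5 AND FDR < 0.05`,
  pooled and per-region.

The methods vignette (`vignettes/pangenome-evolution.Rmd`) derives each
model, documents parameter defaults and numerical conventions, and
states what the simulators do and do not emulate.

## Worked example

```r
library(pangloss)

# a 200-genome collection with a known Heaps decay exponent of 1.5
sim  <- simulate_pangenome(n_genomes = 200, n_core = 100,
                           accessory_pool = 2000, heaps_alpha = 1.5,
                           seed = 42)
part <- partition_pangenome(sim$matrix)
curves <- accumulation_curves(sim$matrix, n_permutations = 1000, seed = 43)
fit  <- fit_heaps(curves)

# a genome with 50 planted compositionally alien genes among 450 natives
cds   <- simulate_cds(n_native = 450, n_alien = 50, seed = 44)
cm    <- codon_metrics(cds$annotation)
flags <- call_hchtg(cm$profiles, cm$thresholds)

# asymmetric Wagner parsimony on a quartet with presence in {A, C}
tree <- ape::read.tree(text = "((A,B),(C,D));")
ev   <- wagner_events(tree, c(A = 1, B = 0, C = 1, D = 0))
```

printed results:

```
core 158 | soft-core 38 | shell 1358 | cloud 546
alpha = 1.454, kappa = 663.3, R2 = 0.998 -> closed pangenome
49 hcHTG calls, 49 of them planted aliens
cost 4: 1 gain, 2 losses, root present
```

The fitted exponent recovers the planted 1.5 within the estimator's
±0.15 operating tolerance and the verdict is closed; the four-factor
screen calls 49 hcHTGs, all planted aliens (sensitivity 0.98 at zero
false positives here); on the quartet both reconstructions cost 4 and
the deterministic tie-break (fewer gains, then absence) reports one
origin gain plus losses on B and D.

## The analysis workflow

`analysis/01_simulate_inputs.R` … `06_cooccurrence.R` run the whole
pipeline end to end on simulated data written in the standard on-disk
formats (Rtab, FASTA + GFF3, Newick, TSV), each stage reading only the
files of `results/inputs/` and writing its tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

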