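#!/usr/bin/env Rscript
# Generates every input the downstream analyses consume, with known
# ground truth, and writes them in the standard on-disk formats under
# results/inputs/.  All later scripts read only these files.

suppressPackageStartupMessages(library(pangloss))
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260901

## pangenome matrix for the openness analysis (closed regime)
pan <- simulate_pangenome(200, n_core = 100, accessory_pool = 2000,
                          heaps_alpha = 1.5, seed = seed)
write_presence_absence(pan$matrix, file.path(out, "pangenome.Rtab"))
write_report(pan$truth, file.path(out, "pangenome_truth.tsv"),
             list(seed = seed, heaps_alpha = 1.5))

## structured matrix for clustering: three subpopulations, each carrying
## a private block of accessory families on top of a shared background
set.seed(seed + 1)
groups <- rep(1:3, each = 20)
bg <- simulate_pangenome(60, n_core = 80, accessory_pool = 400,
                         heaps_alpha = 1.0, seed = seed + 2)$matrix
blocks <- matrix(0L, 60, 120,
                 dimnames = list(rownames(bg), sprintf("grp_%03d", 1:120)))
for (g in 1:3) {
  cols <- (g - 1) * 40 + 1:40
  rows <- which(groups == g)
  blocks[rows, cols] <- matrix(rbinom(length(rows) * 40, 1, 0.9),
                               length(rows))
}
struct <- suppressWarnings(validate_pa_matrix(cbind(bg, blocks)))
write_presence_absence(struct, file.path(out, "structured.Rtab"))
## geography correlated with the subpopulations (plus noise)
region_pool <- c("Europe", "Asia", "North_America")
region <- ifelse(runif(60) < 0.7, region_pool[groups],
                 sample(region_pool, 60, replace = TRUE))
write_report(data.frame(genome_id = rownames(struct), group = groups,
                        region = region),
             file.path(out, "genome_metadata.tsv"), list(seed = seed + 1))

## one genome of codon-biased CDS with planted aliens and transposases
cds <- simulate_cds(n_native = 950, n_alien = 50, n_transposase = 15,
                    transposase_placement = "near_alien", seed = seed + 3)
write_genome_annotation(cds$annotation, cds$contigs,
                        file.path(out, "genome.fna"),
                        file.path(out, "genome.gff"))
write_report(cds$truth, file.path(out, "cds_truth.tsv"),
             list(seed = seed + 3))

## tree + gene histories for the gain/loss analysis
set.seed(seed + 4)
tree <- ape::rcoal(64)
tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
ape::write.tree(tree, file.path(out, "core_tree.nwk"))
gh <- simulate_gene_histories(tree, 500, gain_rate = 0.2, loss_rate = 0.4,
                              root_presence_prob = 0.4, seed = seed + 5)
write_presence_absence(suppressWarnings(validate_pa_matrix(gh$matrix)),
                       file.path(out, "histories.Rtab"))
ev_truth <- data.frame(cog_id = colnames(gh$matrix),
                       true_gains = colSums(gh$gain_events),
                       true_losses = colSums(gh$loss_events))
write_report(ev_truth, file.path(out, "histories_truth.tsv"),
             list(seed = seed + 5, gain_rate = 0.2, loss_rate = 0.4))

## abundance table with planted associations, stratified by region
ab <- simulate_abundance(n_samples = 500, n_taxa = 200,
                         n_planted_positive = 10, n_planted_negative = 10,
                         association_strength = 0.5, seed = seed + 6)
write_abundance(ab$abundance, file.path(out, "abundance.tsv"),
                ab$metadata, file.path(out, "sample_metadata.tsv"))
write_report(data.frame(taxon = c(ab$truth$positive, ab$truth$negative),
                        planted_sign = rep(c("positive", "negative"),
                                           each = 10)),
             file.path(out, "abundance_truth.tsv"), list(seed = seed + 6))

message("inputs written to ", out)
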