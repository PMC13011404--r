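#!/usr/bin/env Rscript
# Gene-content clustering of the structured genome collection: Jaccard
# distances, UPGMA with elbow k selection, PCoA, per-family influence on
# the ordination, and cluster-geography enrichment.

suppressPackageStartupMessages(library(pangloss))
out <- "results/clustering"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260903

m <- parse_presence_absence("results/inputs/structured.Rtab", "rtab")
md <- read.delim("results/inputs/genome_metadata.tsv", comment.char = "#")

d <- jaccard_distance(m)
write_square_tsv(d, file.path(out, "jaccard_distance.tsv"))

cl <- hca_cluster(d, k_max = 10)
message(sprintf("elbow method selects k = %d clusters", cl$k))
write_report(data.frame(genome_id = names(cl$labels), cluster = cl$labels),
             file.path(out, "cluster_labels.tsv"),
             list(linkage = cl$linkage, k = cl$k))
write_report(data.frame(k = seq_along(cl$wcss_curve), wcss = cl$wcss_curve),
             file.path(out, "wcss_curve.tsv"), list(k_max = 10))

pc <- pcoa(d, n_axes = 3)
write_report(data.frame(genome_id = rownames(pc$coordinates),
                        pc$coordinates),
             file.path(out, "pcoa_coordinates.tsv"),
             list(variance_explained =
                    paste(round(pc$variance_explained, 3), collapse = ",")))

# influence of the variable accessory families on the ordination
acc <- m[, colSums(m) > 0 & colSums(m) < nrow(m), drop = FALSE]
inf <- gene_influence(pc, acc, n_permutations = 1000, seed = seed)
write_report(inf, file.path(out, "gene_influence.tsv"),
             list(n_permutations = 1000, seed = seed))
sig <- attr(inf, "significant_genes")
message(sprintf("%d of %d variable families (%.2f%%) significantly influence the ordination",
                length(sig), ncol(acc), 100 * length(sig) / ncol(acc)))
message(sprintf("  of these, %d are planted group-specific families",
                sum(grepl("^grp_", sig))))

enr <- categorical_enrichment(paste0("cluster", cl$labels), md$region)
write_report(enr, file.path(out, "cluster_region_enrichment.tsv"),
             list(thresholds = "p<1e-5 & FDR<0.05"))
message(sprintf("%d cluster-region pairs pass the dual significance threshold",
                sum(enr$significant)))
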