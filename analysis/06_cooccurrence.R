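#!/usr/bin/env Rscript
# Stratified Spearman co-occurrence network of the focal taxon against
# all partners, with BH FDR and the dual significance threshold.

suppressPackageStartupMessages(library(pangloss))
out <- "results/cooccurrence"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tab <- read_abundance("results/inputs/abundance.tsv",
                      "results/inputs/sample_metadata.tsv")
truth <- read.delim("results/inputs/abundance_truth.tsv", comment.char = "#")

ts <- taxon_summaries(tab, group_by = "region")
write_report(ts, file.path(out, "taxon_summaries.tsv"),
             list(group_by = "region"))
focal_all <- ts[ts$stratum == "all" & ts$taxon_id == "focal_sp", ]
message(sprintf("focal taxon: mean abundance %.2f%%, prevalence %.1f%%",
                focal_all$mean_abundance, 100 * focal_all$prevalence))

net <- spearman_network(tab, "focal_sp", strata = "region")
write_report(net, file.path(out, "correlations.tsv"),
             list(thresholds = "p<1e-5 & FDR<0.05", min_prevalence = 0.05))

pooled <- net[net$stratum == "all" & net$significant, ]
message(sprintf("pooled network: %d significant partners (%d positive, %d negative)",
                nrow(pooled), sum(pooled$sign == "positive"),
                sum(pooled$sign == "negative")))
idx <- match(truth$taxon, pooled$partner_taxon)
message(sprintf("  planted associations recovered with correct sign: %d / %d",
                sum(!is.na(idx) & truth$planted_sign == pooled$sign[idx]),
                nrow(truth)))
for (lev in setdiff(unique(net$stratum), "all")) {
  s <- net[net$stratum == lev & net$significant, ]
  message(sprintf("  %s: %d significant (%d+/%d-)", lev, nrow(s),
                  sum(s$sign == "positive"), sum(s$sign == "negative")))
}
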