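#' Bundled reference summary tables
#'
#' Two small published survey summaries for the six human-associated
#' *Bifidobacterium* species are bundled as plain TSV:
#' `"cooccurrence_summary"` — per-species (and, for *B. adolescentis*,
#' per-region) abundance, prevalence and significant positive/negative
#' co-occurrence counts across 10,620 adult gut metagenomes; and
#' `"crispr_subtypes"` — counts of CRISPR-Cas systems by subtype.  They
#' support internal-consistency checks (e.g. that positive + negative
#' correlation counts reproduce the reported totals) without any
#' external download.
#'
#' @param name which table to load.
#' @return A data frame.
#' @export
reference_table <- function(name = c("cooccurrence_summary",
                                     "crispr_subtypes")) {
  name <- match.arg(name)
  f <- switch(name,
    cooccurrence_summary = "bifidobacterium_cooccurrence_summary.tsv",
    crispr_subtypes = "crispr_subtype_counts.tsv")
  path <- system.file("extdata", f, package = "pangloss", mustWork = TRUE)
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
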