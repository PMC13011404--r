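# Readers and writers for the external formats the pipeline touches:
# Roary-style presence/absence matrices (.Rtab and gene_presence_absence.csv),
# FASTA + GFF3 genome annotation, Newick trees, square distance/identity
# matrices, and abundance tables with per-sample metadata.

# Fixed leading columns of Roary's gene_presence_absence.csv; everything
# after them is a genome column.
.roary_fixed_cols <- c(
  "Gene", "Non-unique Gene name", "Annotation", "No. isolates",
  "No. sequences", "Avg sequences per isolate", "Genome Fragment",
  "Order within Fragment", "Accessory Fragment",
  "Accessory Order with Fragment", "QC", "Min group size nuc",
  "Max group size nuc", "Avg group size nuc")

#' Read a gene presence/absence matrix
#'
#' Reads either a Roary `.Rtab` file (genes x genomes, tab separated,
#' entries 0/1) or a Roary `gene_presence_absence.csv` (fixed metadata
#' columns followed by one column per genome holding locus tags).  The
#' result is oriented genomes x gene families.  In the CSV dialect any
#' non-empty cell — including multi-locus paralog cells — is binarised
#' to presence.
#'
#' @param path file path.
#' @param dialect `"rtab"` or `"roary_csv"`.
#' @return Integer matrix (genomes x families) with 0/1 entries; all-zero
#'   families are dropped with a warning.
#' @export
parse_presence_absence <- function(path, dialect = c("rtab", "roary_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) pg_stop("file not found: %s", path)
  if (dialect == "rtab") {
    nf <- count.fields(path, sep = "\t", quote = "\"")
    if (length(unique(nf)) != 1)
      pg_stop("ragged Rtab file %s: line %d has %d fields (expected %d)",
              path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genomes <- colnames(tab)[-1]
    if (anyDuplicated(genomes))
      pg_stop("duplicate genome column in %s: %s", path,
              genomes[duplicated(genomes)][1])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    bad <- which(matrix(!(vals %in% c(0, 1)), nrow(vals)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      pg_stop("non-binary entry '%s' in %s at gene '%s', genome '%s'",
              vals[bad[1, 1], bad[1, 2]], path, tab[[1]][bad[1, 1]],
              genomes[bad[1, 2]])
    m <- t(vals)
    rownames(m) <- genomes
    colnames(m) <- tab[[1]]
  } else {
    nf <- count.fields(path, sep = ",", quote = "\"")
    if (length(unique(nf)) != 1)
      pg_stop("ragged CSV file %s: line %d has %d fields (expected %d)",
              path, which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1])
    tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
    fixed <- intersect(.roary_fixed_cols, colnames(tab))
    if (!"Gene" %in% fixed)
      pg_stop("%s lacks Roary's 'Gene' column", path)
    genome_cols <- setdiff(colnames(tab), .roary_fixed_cols)
    if (anyDuplicated(genome_cols))
      pg_stop("duplicate genome column in %s: %s", path,
              genome_cols[duplicated(genome_cols)][1])
    if (length(genome_cols) == 0) pg_stop("%s has no genome columns", path)
    vals <- as.matrix(tab[, genome_cols, drop = FALSE])
    m <- t(ifelse(is.na(vals) | vals == "", 0L, 1L))
    rownames(m) <- genome_cols
    colnames(m) <- tab[["Gene"]]
  }
  validate_pa_matrix(m)
}

#' Write a presence/absence matrix as Rtab
#'
#' @param m genomes x families binary matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_presence_absence <- function(m, path) {
  m <- validate_pa_matrix(m)
  out <- data.frame(Gene = colnames(m), t(m), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CDS annotation from GFF3 + FASTA
#'
#' Imports GFF3 CDS features, extracts each coding sequence from the
#' matching FASTA contig (1-based inclusive coordinates) and returns the
#' strand-resolved CDS so that codon 1 is the initiator; minus-strand
#' features are reverse-complemented.  CDS whose length is not divisible
#' by 3 are kept but flagged `codon_ok = FALSE` (and a warning is issued)
#' so codon analyses can exclude them.
#'
#' @param gff_path GFF3 file with CDS features.
#' @param fasta_path FASTA file with the contigs the GFF refers to.
#' @return A data frame with columns `contig_id`, `gene_id`, `start`,
#'   `end`, `strand`, `product`, `cds_sequence`, `codon_ok`.
#' @export
parse_genome_annotation <- function(gff_path, fasta_path) {
  gr <- rtracklayer::import(gff_path)
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  if (length(gr) == 0) pg_stop("no CDS features in %s", gff_path)
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))

  contig <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(contig), names(contigs))
  if (length(missing) > 0)
    pg_stop("CDS features reference contigs absent from %s: %s",
            fasta_path, paste(missing, collapse = ", "))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  too_far <- en > Biostrings::width(contigs)[match(contig, names(contigs))] | st < 1
  if (any(too_far))
    pg_stop("CDS coordinates out of contig range (first offender: %s:%d-%d)",
            contig[too_far][1], st[too_far][1], en[too_far][1])

  mc <- S4Vectors::mcols(gr)
  gene_id <- if (!is.null(mc$ID)) as.character(mc$ID)
             else if (!is.null(mc$locus_tag)) as.character(mc$locus_tag)
             else sprintf("cds_%05d", seq_along(gr))
  product <- if (!is.null(mc$product)) as.character(mc$product) else NA_character_

  seqs <- Biostrings::DNAStringSet(lapply(seq_along(gr), function(i) {
    s <- Biostrings::subseq(contigs[[contig[i]]], st[i], en[i])
    if (as.character(GenomicRanges::strand(gr)[i]) == "-")
      s <- Biostrings::reverseComplement(s)
    s
  }))
  len_ok <- Biostrings::width(seqs) %% 3L == 0L
  if (any(!len_ok))
    pg_warn("%d CDS with length not divisible by 3 flagged for exclusion from codon analyses (e.g. %s)",
            sum(!len_ok), gene_id[!len_ok][1])

  data.frame(
    contig_id = contig, gene_id = gene_id, start = st, end = en,
    strand = as.character(GenomicRanges::strand(gr)), product = product,
    cds_sequence = as.character(seqs), codon_ok = len_ok,
    stringsAsFactors = FALSE)
}

#' Write an annotation collection as FASTA + GFF3
#'
#' Counterpart of [parse_genome_annotation()] used mainly to materialise
#' simulated genomes on disk.
#'
#' @param annotation annotation data frame (see [parse_genome_annotation()]).
#' @param contigs named character vector or `DNAStringSet` of contig
#'   sequences.
#' @param fasta_path,gff_path output paths.
#' @return `gff_path`, invisibly.
#' @export
write_genome_annotation <- function(annotation, contigs, fasta_path, gff_path) {
  if (!methods::is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(contigs, fasta_path)
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig_id,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "pangloss"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- annotation$gene_id
  S4Vectors::mcols(gr)$product <- annotation$product
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(gff_path)
}

#' Read a rooted Newick tree
#'
#' Wraps [ape::read.tree()] with the checks the downstream parsimony
#' stage needs: unique tip labels and a rooted topology.  Missing branch
#' lengths default to 1 (logged).
#'
#' @param path Newick file.
#' @return An `ape` `phylo` object.
#' @export
parse_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) pg_stop("cannot parse Newick file %s: %s",
                                             path, conditionMessage(e)))
  if (is.null(tr)) pg_stop("cannot parse Newick file %s", path)
  if (anyDuplicated(tr$tip.label))
    pg_stop("duplicate tip labels in %s: %s", path,
            paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(tr))
    pg_stop("tree in %s is unrooted; root it before gain/loss analyses", path)
  if (is.null(tr$edge.length)) {
    pg_log("tree %s has no branch lengths; defaulting to 1", path)
    tr$edge.length <- rep(1, nrow(tr$edge))
  }
  tr
}

#' Read / write a square labelled matrix as TSV
#'
#' The layout is a header row of labels and a leading label column;
#' used for pairwise identity (gANI) and distance matrices.
#'
#' @param path file path.
#' @return Numeric square matrix with matching dimnames.
#' @export
read_square_tsv <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    pg_stop("%s is not a square labelled matrix", path)
  m
}

#' @rdname read_square_tsv
#' @param m square matrix to write.
#' @export
write_square_tsv <- function(m, path) {
  stopifnot(nrow(m) == ncol(m))
  out <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an abundance table with optional sample metadata
#'
#' The abundance table is samples x taxa (TSV, leading sample-id column),
#' values are relative abundances in percent.  Metadata is a TSV with a
#' `sample_id` column plus e.g. `region` and `age_class`.
#'
#' @param table_path abundance TSV.
#' @param metadata_path optional metadata TSV.
#' @return List with `abundance` (numeric matrix) and `metadata`
#'   (data frame or `NULL`, ordered as the abundance rows).
#' @export
read_abundance <- function(table_path, metadata_path = NULL) {
  ab <- as.matrix(read.delim(table_path, row.names = 1, check.names = FALSE))
  if (any(ab < 0)) pg_stop("negative abundance in %s", table_path)
  if (any(rowSums(ab) > 100 + 1e-6))
    pg_stop("per-sample abundance sums exceed 100%% in %s", table_path)
  md <- NULL
  if (!is.null(metadata_path)) {
    md <- read.delim(metadata_path, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(md))
      pg_stop("metadata %s lacks a sample_id column", metadata_path)
    miss <- setdiff(rownames(ab), md$sample_id)
    if (length(miss) > 0)
      pg_stop("metadata %s lacks samples: %s", metadata_path,
              paste(utils::head(miss, 5), collapse = ", "))
    md <- md[match(rownames(ab), md$sample_id), , drop = FALSE]
  }
  list(abundance = ab, metadata = md)
}

#' @rdname read_abundance
#' @param abundance samples x taxa matrix.
#' @param metadata optional metadata data frame.
#' @export
write_abundance <- function(abundance, table_path, metadata = NULL,
                            metadata_path = NULL) {
  out <- data.frame(sample_id = rownames(abundance), abundance,
                    check.names = FALSE)
  write.table(out, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata) && !is.null(metadata_path))
    write.table(metadata, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(table_path)
}
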