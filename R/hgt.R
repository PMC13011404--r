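# Four-factor codon-usage/GC screen for horizontally transferred genes:
# per-gene RSCU deviation, effective number of codons (Wright), codon
# adaptation index, and GC content, with per-genome nearest-rank
# percentile thresholds and mobile-element context annotation.

# codon/family bookkeeping for the (bacterial) code; stop codons and the
# single-codon families Met/Trp are excluded from RSCU-derived statistics
.codon_tables <- local({
  code <- NULL
  function() {
    if (is.null(code)) {
      gc <- Biostrings::GENETIC_CODE
      fam <- split(names(gc), unname(gc))
      fam[["*"]] <- NULL
      sizes <- lengths(fam)
      deg <- fam[sizes > 1]
      code <<- list(
        codons = names(gc),
        families = fam,
        degenerate = deg,
        fam_of_codon = stats::setNames(rep(names(deg), lengths(deg)),
                                       unlist(deg)),
        fam_sizes = lengths(deg))
    }
    code
  }
})

# counts: genes x 64 codon count matrix for the degenerate codons only
.rscu_from_counts <- function(counts) {
  ct <- .codon_tables()
  rscu <- matrix(NA_real_, nrow(counts), length(ct$fam_of_codon),
                 dimnames = list(rownames(counts), names(ct$fam_of_codon)))
  for (f in names(ct$degenerate)) {
    cods <- ct$degenerate[[f]]
    x <- counts[, cods, drop = FALSE]
    tot <- rowSums(x)
    vals <- x * length(cods) / ifelse(tot > 0, tot, NA)
    vals[tot == 0, ] <- NA
    rscu[, cods] <- vals
  }
  rscu
}

.wright_enc <- function(counts) {
  ct <- .codon_tables()
  n_genes <- nrow(counts)
  fbar <- list()
  for (s in c(2, 3, 4, 6)) {
    fams <- names(ct$degenerate)[ct$fam_sizes == s]
    Fv <- sapply(fams, function(f) {
      x <- counts[, ct$degenerate[[f]], drop = FALSE]
      n <- rowSums(x)
      p2 <- rowSums((x / ifelse(n > 0, n, NA))^2)
      Fx <- (n * p2 - 1) / (n - 1)
      Fx[n < 2] <- NA
      Fx[!is.na(Fx) & Fx <= 0] <- NA        # F = 0 leaves 1/F undefined
      Fx
    })
    if (n_genes == 1) Fv <- matrix(Fv, nrow = 1)
    fbar[[as.character(s)]] <- rowMeans(Fv, na.rm = TRUE)
  }
  f2 <- fbar[["2"]]; f3 <- fbar[["3"]]; f4 <- fbar[["4"]]; f6 <- fbar[["6"]]
  # a wholly absent size class (other than the three-fold one) is imputed
  # from the mean of the available class means
  cls_mean <- rowMeans(cbind(f2, f4, f6), na.rm = TRUE)
  f2 <- ifelse(is.nan(f2), cls_mean, f2)
  f4 <- ifelse(is.nan(f4), cls_mean, f4)
  f6 <- ifelse(is.nan(f6), cls_mean, f6)
  # Wright's imputation for the single three-fold family (Ile)
  f3 <- ifelse(is.nan(f3), (f2 + f4) / 2, f3)
  enc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  pmin(pmax(enc, 20), 61)
}

.cai_weights <- function(ref_counts) {
  ct <- .codon_tables()
  ref <- ref_counts + 0.5                    # pseudocount
  w <- stats::setNames(rep(NA_real_, length(ct$fam_of_codon)),
                       names(ct$fam_of_codon))
  for (f in names(ct$degenerate)) {
    cods <- ct$degenerate[[f]]
    rs <- ref[cods] * length(cods) / sum(ref[cods])
    w[cods] <- rs / max(rs)
  }
  w
}

#' Per-gene codon-usage metrics and per-genome thresholds
#'
#' Computes, for every codon-clean CDS of one genome: the 64-codon count
#' vector; RSCU (relative synonymous codon usage, per codon: observed
#' count times family size over family total); `rscu_deviation`, the mean
#' absolute difference between the gene's RSCU and the genome-average
#' RSCU (pooled counts) over codons whose family is observed in the gene;
#' ENC per Wright (`2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, family homozygosity
#' `F = (n * sum(p^2) - 1)/(n - 1)`, families with `n < 2` or undefined
#' `F` excluded, a missing three-fold mean imputed as `(F2 + F4)/2`,
#' result capped to `[20, 61]`); CAI, the count-weighted geometric mean
#' of relative adaptiveness `w = RSCU_ref / max(family RSCU_ref)` against
#' a highly-expressed reference set; and GC fraction.  Stop codons and
#' the single-codon families Met/Trp never enter RSCU-derived statistics.
#'
#' The CAI reference defaults to genes whose product annotation contains
#' "ribosomal protein"; when fewer than 20 such genes exist, the 5% of
#' genes with lowest ENC are used instead.  Reference counts receive a
#' +0.5 pseudocount.
#'
#' Nearest-rank percentile thresholds (90th for GC, RSCU deviation and
#' ENC; 10th for CAI) are returned alongside; a genome with fewer than 50
#' usable genes yields `NULL` thresholds with a warning.
#'
#' @param genes annotation data frame (see [parse_genome_annotation()]);
#'   genes with `codon_ok = FALSE` or internal stop codons are excluded
#'   with a warning.
#' @param reference_gene_ids optional explicit CAI reference gene ids.
#' @param genome_id label recorded in the thresholds.
#' @return List with `profiles` (data frame: `gene_id`, `gc`,
#'   `rscu_deviation`, `enc`, `cai`), `rscu` and `codon_counts` matrices,
#'   `thresholds` (named list) and `reference_ids`.
#' @export
codon_metrics <- function(genes, reference_gene_ids = NULL,
                          genome_id = "genome_1") {
  if (nrow(genes) == 0) pg_stop("empty gene set")
  ct <- .codon_tables()
  ok <- genes$codon_ok & nchar(genes$cds_sequence) %% 3 == 0
  if (any(!ok))
    pg_warn("excluding %d genes with CDS length not divisible by 3", sum(!ok))
  genes <- genes[ok, , drop = FALSE]
  if (nrow(genes) == 0) pg_stop("no codon-clean genes left")

  seqs <- Biostrings::DNAStringSet(genes$cds_sequence)
  counts <- Biostrings::trinucleotideFrequency(seqs, step = 3)
  rownames(counts) <- genes$gene_id

  # internal stop codons (any stop before the final codon)
  stops <- c("TAA", "TAG", "TGA")
  last_cod <- substr(genes$cds_sequence,
                     nchar(genes$cds_sequence) - 2, nchar(genes$cds_sequence))
  stop_counts <- rowSums(counts[, stops, drop = FALSE])
  internal_stop <- stop_counts > (last_cod %in% stops)
  if (any(internal_stop)) {
    pg_warn("excluding %d genes with internal stop codons", sum(internal_stop))
    genes <- genes[!internal_stop, , drop = FALSE]
    counts <- counts[!internal_stop, , drop = FALSE]
  }
  if (nrow(genes) == 0) pg_stop("no genes without internal stops left")

  rscu <- .rscu_from_counts(counts)
  pooled <- colSums(counts)
  genome_rscu <- .rscu_from_counts(matrix(pooled, 1,
                                          dimnames = list("genome",
                                                          names(pooled))))[1, ]
  rscu_dev <- vapply(seq_len(nrow(rscu)), function(i) {
    obs <- rscu[i, ]
    use <- !is.na(obs) & !is.na(genome_rscu)
    if (!any(use)) return(NA_real_)
    mean(abs(obs[use] - genome_rscu[use]))
  }, 0)

  enc <- .wright_enc(counts)

  gcv <- vapply(strsplit(genes$cds_sequence, ""), function(b)
    mean(b %in% c("G", "C", "g", "c")), 0)

  ref_ids <- reference_gene_ids
  if (is.null(ref_ids)) {
    rib <- genes$gene_id[grepl("ribosomal protein", genes$product,
                               ignore.case = TRUE)]
    if (length(rib) >= 20) {
      ref_ids <- rib
    } else {
      n_low <- max(1L, ceiling(0.05 * nrow(genes)))
      ref_ids <- genes$gene_id[order(enc)][seq_len(n_low)]
      pg_log("CAI reference: %d ribosomal-protein genes < 20; falling back to the %d lowest-ENC genes",
             length(rib), n_low)
    }
  }
  if (!any(genes$gene_id %in% ref_ids))
    pg_stop("no CAI reference genes resolvable (tried explicit ids, 'ribosomal protein' products, lowest-ENC fallback)")
  w <- .cai_weights(colSums(counts[genes$gene_id %in% ref_ids, , drop = FALSE]))
  cods_w <- names(w)[!is.na(w)]
  cai <- vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, cods_w]
    tot <- sum(x)
    if (tot == 0) return(NA_real_)
    exp(sum(x * log(w[cods_w])) / tot)
  }, 0)

  profiles <- data.frame(gene_id = genes$gene_id, gc = gcv,
                         rscu_deviation = rscu_dev, enc = enc, cai = cai,
                         stringsAsFactors = FALSE, row.names = NULL)
  thresholds <- NULL
  if (nrow(profiles) < 50) {
    pg_warn("genome %s has %d usable genes (< 50); percentile thresholds skipped",
            genome_id, nrow(profiles))
  } else {
    thresholds <- list(genome_id = genome_id,
                       gc_p90 = nearest_rank(profiles$gc, 0.9),
                       rscu_dev_p90 = nearest_rank(profiles$rscu_deviation, 0.9),
                       enc_p90 = nearest_rank(profiles$enc, 0.9),
                       cai_p10 = nearest_rank(profiles$cai, 0.1),
                       n_genes_used = nrow(profiles))
  }
  list(profiles = profiles, rscu = rscu, codon_counts = counts,
       thresholds = thresholds, reference_ids = ref_ids)
}

#' Call high-confidence horizontally transferred genes
#'
#' A factor flags a gene when its value falls in the genome's extreme
#' decile: above the nearest-rank 90th percentile for GC, RSCU deviation
#' and ENC, below the 10th percentile for CAI.  A gene with all four
#' flags TRUE is a high-confidence horizontally transferred gene
#' (hcHTG).  `abs_deviation` mode replaces GC with the absolute deviation
#' from the genome median GC before thresholding (so low-GC aliens can
#' flag too).
#'
#' @param profiles profiles data frame from [codon_metrics()].
#' @param thresholds thresholds list from the same [codon_metrics()] call.
#' @param mode `"raw_tail"` (default) or `"abs_deviation"`.
#' @return Data frame (`gene_id`, `flag_gc`, `flag_rscu`, `flag_enc`,
#'   `flag_cai`, `is_hchtg`, `near_transposase` initialised `NA`).
#' @export
call_hchtg <- function(profiles, thresholds, mode = c("raw_tail",
                                                      "abs_deviation")) {
  mode <- match.arg(mode)
  if (is.null(thresholds))
    pg_stop("thresholds unavailable (genome below the 50-gene minimum?)")
  if (!is.null(thresholds$n_genes_used) &&
      thresholds$n_genes_used != nrow(profiles))
    pg_stop("profiles and thresholds disagree on gene count; mixed-genome input?")
  gc_val <- profiles$gc
  gc_thr <- thresholds$gc_p90
  if (mode == "abs_deviation") {
    gc_val <- abs(profiles$gc - median(profiles$gc))
    gc_thr <- nearest_rank(gc_val, 0.9)
  }
  out <- data.frame(
    gene_id = profiles$gene_id,
    flag_gc = gc_val > gc_thr,
    flag_rscu = profiles$rscu_deviation > thresholds$rscu_dev_p90,
    flag_enc = profiles$enc > thresholds$enc_p90,
    flag_cai = profiles$cai < thresholds$cai_p10,
    stringsAsFactors = FALSE)
  out$is_hchtg <- out$flag_gc & out$flag_rscu & out$flag_enc & out$flag_cai
  out$near_transposase <- NA
  out
}

#' Annotate mobile-element context within a window
#'
#' Sets `near_transposase` TRUE for a gene when some gene on the same
#' contig whose product annotation contains one of the marker terms
#' (case-insensitive) lies within `window_nt` of it.  The gap is the
#' nucleotide distance between nearest feature boundaries (overlap
#' counts as 0; the window bound is inclusive).
#'
#' @param flags flags data frame from [call_hchtg()].
#' @param annotation annotation data frame with coordinates for the
#'   flagged genes.
#' @param window_nt window size in nucleotides (default 2000).
#' @param markers marker terms (default `"transposase"`).
#' @return `flags` with `near_transposase` filled in (`NA` where the gene
#'   has no coordinates).
#' @export
mobile_context <- function(flags, annotation, window_nt = 2000,
                           markers = "transposase") {
  pat <- paste(markers, collapse = "|")
  is_marker <- grepl(pat, annotation$product, ignore.case = TRUE)
  mk <- annotation[is_marker, , drop = FALSE]
  idx <- match(flags$gene_id, annotation$gene_id)
  near <- rep(NA, nrow(flags))
  for (i in seq_len(nrow(flags))) {
    ai <- idx[i]
    if (is.na(ai)) next
    same <- mk$contig_id == annotation$contig_id[ai] &
      mk$gene_id != annotation$gene_id[ai]
    if (!any(same)) { near[i] <- FALSE; next }
    gap <- pmax(0, pmax(annotation$start[ai], mk$start[same]) -
                   pmin(annotation$end[ai], mk$end[same]) - 1)
    near[i] <- any(gap <= window_nt)
  }
  flags$near_transposase <- near
  flags
}
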