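# helper: build an annotation data frame from raw codon vectors
ann_from_codons <- function(codon_lists, products = NULL) {
  seqs <- vapply(codon_lists, paste, "", collapse = "")
  data.frame(
    contig_id = "c1", gene_id = sprintf("gene_%03d", seq_along(seqs)),
    start = 1L, end = nchar(seqs), strand = "+",
    product = if (is.null(products)) "hypothetical protein" else products,
    cds_sequence = seqs, codon_ok = TRUE, stringsAsFactors = FALSE)
}

degenerate_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  fam <- split(names(gc), unname(gc))
  fam[["*"]] <- NULL
  unlist(fam[lengths(fam) > 1], use.names = FALSE)
}

test_that("ENC, RSCU and CAI hit their closed forms", {
  cods <- degenerate_codons()                  # 59 degenerate codons
  uniform <- rep(cods, each = 10)              # every codon 10 times
  one_per_aa <- {
    gc <- Biostrings::GENETIC_CODE
    fam <- split(names(gc), unname(gc)); fam[["*"]] <- NULL
    rep(vapply(fam, `[`, "", 1), each = 10)    # one codon per family
  }
  ann <- ann_from_codons(list(uniform, one_per_aa))
  res <- suppressWarnings(codon_metrics(ann, reference_gene_ids = "gene_001"))

  # uniform synonymous usage: all RSCU = 1, ENC capped at the 61 maximum
  expect_true(all(abs(res$rscu["gene_001", ] - 1) < 1e-12))
  expect_equal(res$profiles$enc[1], 61)
  # one codon per family: every family F = 1, ENC = 20
  expect_equal(res$profiles$enc[2], 20)
  # gene matching the reference usage exactly: CAI = 1 is approached as
  # the pseudocount vanishes; with +0.5 it stays within 1e-3 of 1 here
  expect_equal(res$profiles$cai[1], 1, tolerance = 2e-3)
  # deviation of the uniform gene from a genome average dominated by it
  expect_lt(res$profiles$rscu_deviation[1], res$profiles$rscu_deviation[2])
})

test_that("a reference-optimal gene has CAI 1", {
  # all genes use exactly one codon per family -> that codon is the
  # reference optimum, every weight is 1, geometric mean is exactly 1
  gc <- Biostrings::GENETIC_CODE
  fam <- split(names(gc), unname(gc)); fam[["*"]] <- NULL
  first <- vapply(fam, `[`, "", 1)
  ann <- ann_from_codons(list(rep(first, 5), rep(first, 7)))
  res <- suppressWarnings(codon_metrics(ann, reference_gene_ids = "gene_001"))
  expect_equal(res$profiles$cai, c(1, 1), tolerance = 1e-12)
})

test_that("two-fold family arithmetic matches the direct oracle", {
  # gene of a single 2-fold family with counts (3, 1): RSCU (1.5, 0.5),
  # F = (4 * (9/16 + 1/16) - 1) / 3 = 0.5
  ann <- ann_from_codons(list(c(rep("AAA", 3), "AAG")))   # Lys family
  res <- suppressWarnings(codon_metrics(ann, reference_gene_ids = "gene_001"))
  expect_equal(unname(res$rscu["gene_001", c("AAA", "AAG")]), c(1.5, 0.5))
  # with only one family observed every class mean falls back to F = 0.5:
  # ENC = 2 + 18/... capped into [20, 61]
  expect_true(res$profiles$enc[1] >= 20 && res$profiles$enc[1] <= 61)

  # RSCU family sums equal family sizes on a random gene
  set.seed(1)
  gene <- sample(degenerate_codons(), 600, replace = TRUE)
  ann2 <- ann_from_codons(list(gene))
  r2 <- suppressWarnings(codon_metrics(ann2, reference_gene_ids = "gene_001"))
  gc_map <- Biostrings::GENETIC_CODE
  fams <- split(names(gc_map), unname(gc_map)); fams[["*"]] <- NULL
  for (f in names(fams)[lengths(fams) > 1]) {
    vals <- r2$rscu["gene_001", fams[[f]]]
    if (!any(is.na(vals)))
      expect_equal(sum(vals), length(fams[[f]]), tolerance = 1e-9)
  }
})

test_that("codon metrics are invariant to gene self-concatenation", {
  set.seed(2)
  gene <- sample(degenerate_codons(), 300, replace = TRUE)
  ann <- ann_from_codons(list(gene, c(gene, gene)))
  res <- suppressWarnings(codon_metrics(ann, reference_gene_ids = "gene_001"))
  expect_equal(res$profiles$cai[1], res$profiles$cai[2], tolerance = 1e-9)
  expect_equal(res$rscu["gene_001", ], res$rscu["gene_002", ],
               tolerance = 1e-9)
  # ENC uses within-family frequencies whose F changes only through the
  # (n-1) small-sample factor; doubling length moves it slightly toward
  # the asymptote, never by much
  expect_equal(res$profiles$enc[1], res$profiles$enc[2], tolerance = 0.6)
})

test_that("genes with frame or stop violations are excluded with warnings", {
  good <- rep(c("AAA", "GGC", "TTA"), 30)
  with_stop <- c(rep("AAA", 10), "TAA", rep("GGC", 10))
  ann <- ann_from_codons(list(good, with_stop, rep("AAC", 20)))
  ann$cds_sequence[3] <- "AAAAACA"        # length 7
  ann$codon_ok[3] <- FALSE
  warns <- character(0)
  res <- withCallingHandlers(
    codon_metrics(ann, reference_gene_ids = "gene_001"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_true(any(grepl("not divisible by 3", warns)))
  expect_true(any(grepl("internal stop", warns)))
  expect_identical(res$profiles$gene_id, "gene_001")
})

test_that("percentile flags follow rank arithmetic and the conjunction rule", {
  set.seed(3)
  n <- 100
  base <- data.frame(
    gene_id = sprintf("g%03d", 1:n),
    gc = runif(n, 0.4, 0.6), rscu_deviation = runif(n),
    enc = runif(n, 30, 55), cai = runif(n, 0.2, 0.9))
  # gene 1: rank 95 in the upper-tail factors, 3rd lowest CAI
  base$gc[1] <- sort(base$gc)[95]
  base$gc[1] <- base$gc[1] + 1e-9
  base$rscu_deviation[1] <- max(base$rscu_deviation) - 1e-9
  base$enc[1] <- sort(base$enc)[96]
  base$cai[1] <- sort(base$cai)[3]
  thr <- list(genome_id = "t", gc_p90 = pangloss:::nearest_rank(base$gc, .9),
              rscu_dev_p90 = pangloss:::nearest_rank(base$rscu_deviation, .9),
              enc_p90 = pangloss:::nearest_rank(base$enc, .9),
              cai_p10 = pangloss:::nearest_rank(base$cai, .1),
              n_genes_used = n)
  fl <- call_hchtg(base, thr)
  expect_true(all(unlist(fl[1, c("flag_gc", "flag_rscu", "flag_enc",
                                 "flag_cai")])))
  expect_true(fl$is_hchtg[1])
  # flag rate is 10% up to nearest-rank granularity (strict inequality
  # against the rank-90 value leaves 9 or 10 of 100 continuous values)
  expect_lte(abs(mean(fl$flag_gc) - 0.10), 0.011)
  expect_lte(abs(mean(fl$flag_cai) - 0.10), 0.011)
  # a gene at the genome median flags nothing
  med <- base
  med[2, c("gc", "rscu_deviation", "enc", "cai")] <-
    c(median(base$gc), median(base$rscu_deviation), median(base$enc),
      median(base$cai))
  fl2 <- call_hchtg(med, list(genome_id = "t",
                              gc_p90 = pangloss:::nearest_rank(med$gc, .9),
                              rscu_dev_p90 = pangloss:::nearest_rank(med$rscu_deviation, .9),
                              enc_p90 = pangloss:::nearest_rank(med$enc, .9),
                              cai_p10 = pangloss:::nearest_rank(med$cai, .1),
                              n_genes_used = n))
  expect_false(any(unlist(fl2[2, c("flag_gc", "flag_rscu", "flag_enc",
                                   "flag_cai")])))
})

test_that("mobile-element context windows are boundary-inclusive", {
  ann <- data.frame(
    contig_id = c("c1", "c1", "c1", "c2"),
    gene_id = c("focal", "tp_near", "tp_far", "tp_other"),
    start = c(5000L, 6500L, 99000L, 6500L),
    end = c(6000L, 7000L, 99900L, 7000L),
    strand = "+",
    product = c("hypothetical protein", "IS3 family transposase",
                "transposase", "transposase"),
    cds_sequence = "ATG", codon_ok = TRUE, stringsAsFactors = FALSE)
  fl <- data.frame(gene_id = "focal", flag_gc = TRUE, flag_rscu = TRUE,
                   flag_enc = TRUE, flag_cai = TRUE, is_hchtg = TRUE,
                   stringsAsFactors = FALSE)
  expect_true(mobile_context(fl, ann)$near_transposase)        # gap 499

  ann2 <- ann[c(1, 3, 4), ]
  expect_false(mobile_context(fl, ann2)$near_transposase)      # far + other contig

  # boundary contract: start 8001 -> gap 2000 (TRUE); 8002 -> 2001 (FALSE)
  ann3 <- ann[1:2, ]
  ann3[2, c("start", "end")] <- c(8001L, 9000L)
  expect_true(mobile_context(fl, ann3)$near_transposase)
  ann3[2, c("start", "end")] <- c(8002L, 9000L)
  expect_false(mobile_context(fl, ann3)$near_transposase)
})

test_that("the screen recovers planted aliens on a simulated genome", {
  sim <- simulate_cds(n_native = 400, n_alien = 25, n_ribosomal = 25,
                      seed = 21)
  cm <- codon_metrics(sim$annotation)
  fl <- call_hchtg(cm$profiles, cm$thresholds)
  cls <- sim$truth$class[match(fl$gene_id, sim$truth$gene_id)]
  expect_gte(mean(fl$is_hchtg[cls == "alien"]), 0.8)
  expect_lte(mean(fl$is_hchtg[cls == "native"]), 0.05)
  # abs-deviation mode also catches the planted (high-GC) aliens here
  fl_abs <- call_hchtg(cm$profiles, cm$thresholds, mode = "abs_deviation")
  expect_gte(mean(fl_abs$flag_gc[cls == "alien"]), 0.5)
})
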