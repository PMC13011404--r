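test_that("simulators are deterministic given a seed", {
  a <- simulate_pangenome(20, n_core = 10, accessory_pool = 50, seed = 7)
  b <- simulate_pangenome(20, n_core = 10, accessory_pool = 50, seed = 7)
  expect_identical(a$matrix, b$matrix)
  c1 <- simulate_cds(n_native = 20, n_alien = 3, n_ribosomal = 3, seed = 7)
  c2 <- simulate_cds(n_native = 20, n_alien = 3, n_ribosomal = 3, seed = 7)
  expect_identical(c1$annotation, c2$annotation)
  s1 <- simulate_abundance(n_samples = 25, n_taxa = 8, regions = c(E = 25),
                           n_planted_positive = 2, n_planted_negative = 2,
                           seed = 7)
  s2 <- simulate_abundance(n_samples = 25, n_taxa = 8, regions = c(E = 25),
                           n_planted_positive = 2, n_planted_negative = 2,
                           seed = 7)
  expect_identical(s1$abundance, s2$abundance)
})

test_that("pangenome simulator honours core, cloud cap and truth classes", {
  sim <- simulate_pangenome(60, n_core = 20, accessory_pool = 300,
                            heaps_alpha = 1.0, cloud_fraction = 0.5, seed = 3)
  prev <- colSums(sim$matrix) / nrow(sim$matrix)
  expect_true(all(prev[sim$truth$planted == "core"] == 1))
  # forced-cloud families stay below the 15% cap
  forced <- sim$truth$cog_id[sim$truth$planted == "accessory"][1:150]
  expect_true(all(prev[forced] < 0.15))
  # truth classes equal the partition of the realised matrix
  p <- partition_pangenome(sim$matrix)
  expect_identical(unname(p$class), sim$truth$class)

  # degenerate settings: no accessory pool -> identical genomes
  flat <- simulate_pangenome(5, n_core = 30, accessory_pool = 0, seed = 1)
  cur <- accumulation_curves(flat$matrix, 50, seed = 2)
  expect_equal(cur$mean_new_genes, c(30, 0, 0, 0, 0))

  expect_error(simulate_pangenome(50, accessory_pool = 10, seed = 1),
               "increase the pool")
})

test_that("cds simulator separates native and alien composition", {
  sim <- simulate_cds(n_native = 150, n_alien = 30, n_ribosomal = 20,
                      seed = 11)
  gc_by <- tapply(
    vapply(strsplit(sim$annotation$cds_sequence, ""),
           function(b) mean(b %in% c("G", "C")), 0),
    sim$truth$class[match(sim$annotation$gene_id, sim$truth$gene_id)], mean)
  expect_gt(gc_by[["alien"]], gc_by[["native"]] + 0.05)

  none <- simulate_cds(n_native = 25, n_alien = 0, n_ribosomal = 5, seed = 2)
  expect_true(all(none$truth$class %in% c("native", "transposase")))

  # CDS are frame-clean: start with ATG, end in a stop, no internal stops
  stops <- c("TAA", "TAG", "TGA")
  cods <- substring(sim$annotation$cds_sequence[1],
                    seq(1, nchar(sim$annotation$cds_sequence[1]) - 2, 3),
                    seq(3, nchar(sim$annotation$cds_sequence[1]), 3))
  expect_identical(cods[1], "ATG")
  expect_true(cods[length(cods)] %in% stops)
  expect_false(any(cods[-length(cods)] %in% stops))
})

test_that("transposase placement controls the 2000-nt context", {
  near <- simulate_cds(n_native = 40, n_alien = 10, n_ribosomal = 5,
                       n_transposase = 5,
                       transposase_placement = "near_alien", seed = 9)
  cm_ann <- near$annotation
  tp <- cm_ann[grepl("transposase", cm_ann$product), ]
  al <- cm_ann[cm_ann$gene_id %in%
                 near$truth$gene_id[near$truth$class == "alien"], ]
  gap_to_alien <- vapply(seq_len(nrow(tp)), function(i)
    min(pmax(0, pmax(tp$start[i], al$start) -
                  pmin(tp$end[i], al$end) - 1)), 0)
  expect_true(all(gap_to_alien <= 2000))

  far <- simulate_cds(n_native = 40, n_alien = 10, n_ribosomal = 5,
                      n_transposase = 5, transposase_placement = "far",
                      seed = 9)
  ann <- far$annotation
  tp <- ann[grepl("transposase", ann$product), ]
  ot <- ann[!grepl("transposase", ann$product), ]
  gap_all <- vapply(seq_len(nrow(tp)), function(i)
    min(pmax(0, pmax(tp$start[i], ot$start) -
                  pmin(tp$end[i], ot$end) - 1)), 0)
  expect_true(all(gap_all > 2000))
})

test_that("gene-history simulator respects degenerate rates and parity", {
  tree <- ape::rcoal(12)
  off <- simulate_gene_histories(tree, 20, gain_rate = 0, loss_rate = 0.5,
                                 root_presence_prob = 0, seed = 4)
  expect_true(all(off$matrix == 0))
  expect_true(all(off$gain_events == 0) && all(off$loss_events == 0))

  on <- simulate_gene_histories(tree, 20, gain_rate = 0.5, loss_rate = 0,
                                root_presence_prob = 1, seed = 4)
  expect_true(all(on$matrix == 1))

  # tip state = root state + net events along the root-to-tip path (mod 2)
  gh <- simulate_gene_histories(tree, 30, gain_rate = 0.3, loss_rate = 0.5,
                                root_presence_prob = 0.5, seed = 5)
  ntip <- length(tree$tip.label)
  for (tip in seq_len(ntip)) {
    node <- tip; flips <- numeric(30)
    while (node != ntip + 1) {
      e <- which(tree$edge[, 2] == node)
      flips <- flips + gh$gain_events[e, ] + gh$loss_events[e, ]
      node <- tree$edge[e, 1]
    }
    expect_equal(gh$matrix[tree$tip.label[tip], ],
                 (gh$root_states + flips) %% 2,
                 ignore_attr = TRUE)
  }
})

test_that("abundance simulator plants monotone associations and zeros", {
  sim <- simulate_abundance(n_samples = 100, n_taxa = 30,
                            n_planted_positive = 3, n_planted_negative = 3,
                            association_strength = 0.8,
                            zero_inflation = c(0.2, 1, rep(0.2, 28)),
                            regions = c(E = 60, A = 40), seed = 6)
  # taxon with zero_inflation 1 (first non-focal position) is absent
  zi_taxon <- colnames(sim$abundance)[2]
  expect_equal(sum(sim$abundance[, zi_taxon] > 0), 0)
  expect_true(all(rowSums(sim$abundance) <= 100 + 1e-6))
  expect_true(all(rowSums(sim$abundance) >= 0))
  rho <- cor(sim$abundance[, "focal_sp"],
             sim$abundance[, sim$truth$positive[2]], method = "spearman")
  expect_gt(rho, 0.3)
  expect_error(simulate_abundance(association_strength = 1.2, seed = 1),
               "lower the strength")
})
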