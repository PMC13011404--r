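# Simulators with known ground truth for every input the pipeline
# consumes: presence/absence matrices with a controlled Heaps decay,
# codon-biased CDS with planted compositionally alien genes, gene
# gain/loss histories on a tree, and zero-inflated abundance tables with
# planted monotone associations.

# ---- pangenome ------------------------------------------------------------

# P(a family carried by k of G genomes is first seen at addition step N)
# for N = 1..G, under a uniformly random genome order.
first_occurrence_kernel <- function(G) {
  H <- matrix(0, G, G)
  for (k in 1:G) {
    n1 <- 0:G
    lp <- ifelse(n1 > G - k, -Inf, lchoose(G - k, n1) - lchoose(G, n1))
    pb <- exp(lp)                        # P(no carrier among first n1)
    H[, k] <- pb[1:G] - pb[2:(G + 1)]
  }
  H
}

# Non-negative prevalence mixture w over k = 1..G whose exact expected
# new-family curve under random genome orders is proportional to N^-alpha.
heaps_prevalence_spectrum <- function(G, alpha) {
  H <- first_occurrence_kernel(G)
  target <- (1:G)^(-alpha)
  target <- target / sum(target)         # each family contributes mass 1
  w <- pracma::lsqnonneg(H, target)$x
  if (sum(w) <= 0) pg_stop("could not solve prevalence spectrum for alpha = %g", alpha)
  w / sum(w)
}

#' Simulate a pangenome presence/absence matrix with known Heaps decay
#'
#' Core families are present in every genome.  Each accessory family is
#' given a prevalence `k` drawn from a mixture solved (non-negative least
#' squares against the exact first-occurrence kernel) so that the
#' expected number of novel families contributed by the N-th genome in a
#' random addition order is proportional to `N^-heaps_alpha`; the family
#' is then assigned to a uniformly random `k`-subset of genomes, making
#' genomes exchangeable and the control of the accumulation expectation
#' exact.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param n_core number of core families (present everywhere).
#' @param accessory_pool number of accessory families.
#' @param heaps_alpha target decay exponent of the new-family curve (> 0).
#' @param cloud_fraction optional fraction of accessory families forced
#'   to cloud prevalence (< 15% of genomes).  `NULL` (default) leaves the
#'   spectrum untouched, which preserves the target decay exactly;
#'   forcing a fraction caps prevalences and perturbs the curve.
#' @param seed integer seed.
#' @return List with `matrix` (genomes x families), `truth` (per-family
#'   planted class and prevalence plus `heaps_alpha`), and `params`.
#' @export
simulate_pangenome <- function(n_genomes, n_core = 100, accessory_pool = 2000,
                               heaps_alpha = 1.0, cloud_fraction = NULL,
                               seed = NULL) {
  if (n_genomes < 2) pg_stop("n_genomes must be >= 2")
  if (heaps_alpha < 0) pg_stop("heaps_alpha must be >= 0")
  if (accessory_pool > 0 && accessory_pool < n_genomes)
    pg_stop("accessory_pool (%d) too small for %d genomes; increase the pool",
            accessory_pool, n_genomes)
  set.seed(pg_seed(seed))
  G <- n_genomes
  total <- n_core + accessory_pool
  m <- matrix(0L, G, total,
              dimnames = list(sprintf("genome_%04d", 1:G),
                              c(sprintf("core_%05d", seq_len(n_core)),
                                sprintf("acc_%05d", seq_len(accessory_pool)))))
  if (n_core > 0) m[, seq_len(n_core)] <- 1L

  k <- integer(0)
  if (accessory_pool > 0) {
    w <- heaps_prevalence_spectrum(G, heaps_alpha)
    k <- sample.int(G, accessory_pool, replace = TRUE, prob = w)
    cap <- ceiling(0.15 * G) - 1L
    if (!is.null(cloud_fraction)) {
      stopifnot(cloud_fraction >= 0, cloud_fraction <= 1)
      n_cloud <- round(cloud_fraction * accessory_pool)
      idx <- seq_len(n_cloud)
      k[idx] <- pmin(k[idx], max(cap, 1L))
    }
    for (g in seq_len(accessory_pool))
      m[sample.int(G, k[g]), n_core + g] <- 1L
  }

  prev <- colSums(m) / G
  cls <- ifelse(prev >= 0.99, "core",
         ifelse(prev >= 0.95, "soft_core",
         ifelse(prev >= 0.15, "shell", "cloud")))
  truth <- data.frame(cog_id = colnames(m),
                      planted = c(rep("core", n_core),
                                  rep("accessory", accessory_pool)),
                      class = cls, prevalence = prev,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(matrix = m, truth = truth,
       params = list(n_genomes = n_genomes, n_core = n_core,
                     accessory_pool = accessory_pool,
                     heaps_alpha = heaps_alpha,
                     cloud_fraction = cloud_fraction, seed = seed))
}

# ---- coding sequences -----------------------------------------------------

# synonymous families of the (bacterial) genetic code, stops excluded
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  fam <- split(names(gc), unname(gc))
  fam[["*"]] <- NULL
  fam
}

codon_gc_frac <- function(codons) {
  vapply(strsplit(codons, ""), function(b) mean(b %in% c("G", "C")), 0)
}

# Draw a genome-level codon preference.  Per family, a preferred codon
# is sampled with softmax(eta * GC); within the family the preferred
# codon gets base weight 1/n + bias*(1 - 1/n), the rest share the
# remainder equally, and all base weights receive an exponential GC
# tilt exp(eta * GC_codon).  eta is solved so the expected gene GC hits
# the target; at eta = 0 the weights reduce to the untilted scheme.
draw_preference <- function(target_gc, bias, families) {
  fam_gc <- lapply(families, codon_gc_frac)
  base_w <- function(n, j) {
    if (n == 1) return(1)
    w <- rep((1 - (1 / n + bias * (1 - 1 / n))) / (n - 1), n)
    w[j] <- 1 / n + bias * (1 - 1 / n)
    w
  }
  exp_gc <- function(eta) {
    per_fam <- vapply(seq_along(families), function(i) {
      g <- fam_gc[[i]]; n <- length(g)
      sm <- exp(eta * g); sm <- sm / sum(sm)
      if (n == 1) return(g)
      # expectation over the preferred-codon draw of the gene-level GC
      sum(vapply(seq_len(n), function(j) {
        w <- base_w(n, j) * exp(eta * g)
        w <- w / sum(w)
        sm[j] * sum(w * g)
      }, 0))
    }, 0)
    mean(per_fam)
  }
  lo <- exp_gc(-60); hi <- exp_gc(60)
  if (target_gc < lo || target_gc > hi)
    pg_stop("target GC %.2f outside achievable range (%.2f, %.2f) at bias %.2f",
            target_gc, lo, hi, bias)
  eta <- uniroot(function(e) exp_gc(e) - target_gc, c(-60, 60))$root
  lapply(seq_along(families), function(i) {
    g <- fam_gc[[i]]; n <- length(g)
    sm <- exp(eta * g); sm <- sm / sum(sm)
    j <- sample.int(n, 1, prob = sm)
    w <- base_w(n, j) * exp(eta * g)
    stats::setNames(w / sum(w), families[[i]])
  })
}

sample_gene_codons <- function(n_codons, pref, families) {
  aa <- sample.int(length(families), n_codons, replace = TRUE)
  vapply(aa, function(i) {
    w <- pref[[i]]
    names(w)[sample.int(length(w), 1, prob = w)]
  }, "")
}

#' Simulate codon-biased CDS with planted alien genes
#'
#' Native genes are drawn from one genome-wide codon preference (see
#' Details); alien genes from an independent preference at a different GC
#' and bias, emulating horizontally acquired material.  Genes are laid
#' out on a single contig; transposase-labelled marker genes can be
#' placed near or far from alien genes to exercise the mobile-element
#' context window.
#'
#' @param n_native,n_alien gene counts.
#' @param native_gc,alien_gc target GC fractions (in (0.25, 0.75)).
#' @param native_bias_strength,alien_bias_strength preferred-codon
#'   concentration in `[0, 1]`: 0 = uniform synonymous usage, 1 = only the
#'   preferred codon.
#' @param mean_gene_len_codons mean gene length in codons (Poisson).
#' @param n_ribosomal number of native genes labelled
#'   `"ribosomal protein"` (the default CAI reference).
#' @param n_transposase number of transposase-labelled marker genes.
#' @param transposase_placement `"near_alien"`, `"far"` or `"random"`.
#' @param seed integer seed.
#' @return List with `annotation` (see [parse_genome_annotation()]),
#'   `contigs` (named character), `truth` (per-gene class:
#'   native/alien/transposase) and `params`.
#' @export
simulate_cds <- function(n_native = 950, n_alien = 50,
                         native_gc = 0.45, alien_gc = 0.55,
                         native_bias_strength = 0.6,
                         alien_bias_strength = 0.1,
                         mean_gene_len_codons = 300,
                         n_ribosomal = 30, n_transposase = 0,
                         transposase_placement = c("near_alien", "far", "random"),
                         seed = NULL) {
  transposase_placement <- match.arg(transposase_placement)
  stopifnot(n_native >= 0, n_alien >= 0,
            native_gc > 0.25, native_gc < 0.75,
            alien_gc > 0.25, alien_gc < 0.75)
  set.seed(pg_seed(seed))
  families <- codon_families()
  pref_native <- draw_preference(native_gc, native_bias_strength, families)
  pref_alien <- draw_preference(alien_gc, alien_bias_strength, families)

  n_total <- n_native + n_alien + n_transposase
  classes <- c(rep("native", n_native), rep("alien", n_alien),
               rep("transposase", n_transposase))
  prefs <- c(rep(list(pref_native), n_native), rep(list(pref_alien), n_alien),
             rep(list(pref_native), n_transposase))
  lens <- pmax(50L, rpois(n_total, mean_gene_len_codons))
  seqs <- vapply(seq_len(n_total), function(i) {
    body <- sample_gene_codons(lens[i] - 2L, prefs[[i]], families)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }, "")

  products <- rep("hypothetical protein", n_total)
  rib <- utils::head(which(classes == "native"), n_ribosomal)
  products[rib] <- sprintf("50S ribosomal protein L%d", seq_along(rib))
  products[classes == "transposase"] <- "IS3 family transposase"

  gene_id <- sprintf("%s_%04d", substr(classes, 1, 3), seq_len(n_total))

  # layout: natives and aliens shuffled along the contig; transposases
  # inserted per the placement flag
  base_order <- sample(which(classes != "transposase"))
  tp <- which(classes == "transposase")
  order_final <- base_order
  if (length(tp) > 0) {
    if (transposase_placement == "near_alien" && n_alien > 0) {
      for (t in tp) {
        anchor <- which(classes[order_final] == "alien")
        at <- anchor[sample.int(length(anchor), 1)]
        order_final <- append(order_final, t, after = at)
      }
    } else {
      for (t in tp) order_final <- append(order_final, t,
                                          after = sample(length(order_final), 1))
    }
  }
  gaps <- if (transposase_placement == "far")
    sample(2200:4000, n_total, replace = TRUE)
  else
    sample(50:400, n_total, replace = TRUE)

  pos <- 1L
  start <- integer(n_total); end <- integer(n_total); strand <- character(n_total)
  contig_parts <- character(0)
  for (j in seq_along(order_final)) {
    i <- order_final[j]
    gap <- gaps[j]
    spacer <- paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                    collapse = "")
    s <- pos + gap
    e <- s + nchar(seqs[i]) - 1L
    strand[i] <- sample(c("+", "-"), 1)
    locus <- if (strand[i] == "+") seqs[i] else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[i])))
    contig_parts <- c(contig_parts, spacer, locus)
    start[i] <- s; end[i] <- e
    pos <- e + 1L
  }
  contig <- paste(contig_parts, collapse = "")

  annotation <- data.frame(
    contig_id = "contig_1", gene_id = gene_id, start = start, end = end,
    strand = strand, product = products, cds_sequence = seqs,
    codon_ok = TRUE, stringsAsFactors = FALSE)[order(start), ]
  rownames(annotation) <- NULL
  truth <- data.frame(gene_id = gene_id, class = classes,
                      stringsAsFactors = FALSE)
  list(annotation = annotation, contigs = c(contig_1 = contig), truth = truth,
       params = list(n_native = n_native, n_alien = n_alien,
                     native_gc = native_gc, alien_gc = alien_gc,
                     native_bias_strength = native_bias_strength,
                     alien_bias_strength = alien_bias_strength,
                     mean_gene_len_codons = mean_gene_len_codons,
                     seed = seed))
}

# ---- gene histories on a tree --------------------------------------------

#' Simulate gene gain/loss histories on a rooted tree
#'
#' Each gene family evolves independently by a two-state continuous-time
#' Markov process along the tree (0 -> 1 at `gain_rate`, 1 -> 0 at
#' `loss_rate` per unit branch length) from a Bernoulli root.  True event
#' counts are recorded per branch.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param n_cogs number of gene families.
#' @param gain_rate,loss_rate event rates (>= 0).
#' @param root_presence_prob probability the root carries the family.
#' @param seed integer seed.
#' @return List with `matrix` (tips x families), `root_states`,
#'   `gain_events` and `loss_events` (edges x families count matrices,
#'   rows ordered as `tree$edge`), and `params`.
#' @export
simulate_gene_histories <- function(tree, n_cogs, gain_rate = 0.1,
                                    loss_rate = 0.3,
                                    root_presence_prob = 0.5, seed = NULL) {
  stopifnot(gain_rate >= 0, loss_rate >= 0,
            root_presence_prob >= 0, root_presence_prob <= 1)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    pg_stop("tree must have non-negative branch lengths")
  set.seed(pg_seed(seed))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edges <- tree$edge
  root <- ntip + 1L

  states <- matrix(NA_integer_, ntip + nnode, n_cogs)
  states[root, ] <- rbinom(n_cogs, 1, root_presence_prob)
  gain_ev <- matrix(0L, nrow(edges), n_cogs)
  loss_ev <- matrix(0L, nrow(edges), n_cogs)

  # reverse postorder = preorder over edges (parents before children)
  post <- ape::reorder.phylo(tree, "postorder")
  ord <- rev(match(post$edge[, 2], edges[, 2]))
  for (e in ord) {
    p <- edges[e, 1]; ch <- edges[e, 2]; t_len <- tree$edge.length[e]
    s <- states[p, ]
    g <- integer(n_cogs); l <- integer(n_cogs)
    for (j in seq_len(n_cogs)) {
      t_cur <- 0; sj <- s[j]
      repeat {
        rate <- if (sj == 0L) gain_rate else loss_rate
        if (rate == 0) break
        t_cur <- t_cur + rexp(1, rate)
        if (t_cur > t_len) break
        if (sj == 0L) { sj <- 1L; g[j] <- g[j] + 1L }
        else { sj <- 0L; l[j] <- l[j] + 1L }
      }
      s[j] <- sj
    }
    states[ch, ] <- s
    gain_ev[e, ] <- g
    loss_ev[e, ] <- l
  }

  m <- states[seq_len(ntip), , drop = FALSE]
  dimnames(m) <- list(tree$tip.label, sprintf("cog_%05d", seq_len(n_cogs)))
  colnames(gain_ev) <- colnames(loss_ev) <- colnames(m)
  list(matrix = m, root_states = states[root, ],
       gain_events = gain_ev, loss_events = loss_ev,
       params = list(n_cogs = n_cogs, gain_rate = gain_rate,
                     loss_rate = loss_rate,
                     root_presence_prob = root_presence_prob, seed = seed))
}

# ---- abundance tables -----------------------------------------------------

#' Simulate a zero-inflated abundance table with planted associations
#'
#' Latent Gaussian copula: planted-positive taxa share latent correlation
#' `+association_strength` with the focal taxon, planted-negative
#' `-association_strength` (single-factor construction, always positive
#' definite), all other taxa are independent.  Marginals are log-normal;
#' zero inflation censors each taxon below its own `zero_inflation`
#' quantile (a monotone operation, so the planted rank associations
#' survive as tied zeros); samples are then renormalised to percent.
#'
#' @param n_samples,n_taxa table dimensions.
#' @param n_planted_positive,n_planted_negative planted partner counts.
#' @param association_strength latent correlation magnitude in (0, 1).
#' @param zero_inflation per-taxon absence probability (scalar or length
#'   `n_taxa`); the focal taxon uses `focal_zero_inflation`.
#' @param focal_zero_inflation absence probability of the focal taxon.
#' @param regions named integer vector of per-region sample counts; its
#'   sum must equal `n_samples`.
#' @param unclassified_weight size of the unprofiled community fraction
#'   relative to the expected profiled total (default 9).  Abundances are
#'   expressed in percent of a fixed community size (profiled +
#'   unprofiled material); the fixed denominator is a global monotone
#'   transform, so it cannot induce spurious rank correlations among
#'   unassociated taxa the way per-sample closure would.
#' @param age_classes optional character vector sampled uniformly per
#'   sample.
#' @param seed integer seed.
#' @return List with `abundance` (samples x taxa, percent), `metadata`
#'   (sample_id, region, age_class), `truth` (focal id, planted partner
#'   ids and signs) and `params`.
#' @export
simulate_abundance <- function(n_samples = 500, n_taxa = 200,
                               n_planted_positive = 10,
                               n_planted_negative = 10,
                               association_strength = 0.5,
                               zero_inflation = 0.3,
                               focal_zero_inflation = 0.3,
                               regions = c(Europe = 200, Asia = 150,
                                           North_America = 150),
                               unclassified_weight = 9,
                               age_classes = NULL, seed = NULL) {
  if (association_strength <= 0 || association_strength >= 1)
    pg_stop("association_strength must be in (0, 1); lower the strength")
  if (sum(regions) != n_samples)
    pg_stop("region sample counts (%d) must sum to n_samples (%d)",
            sum(regions), n_samples)
  n_planted <- n_planted_positive + n_planted_negative
  if (n_planted + 1 > n_taxa) pg_stop("too many planted taxa for n_taxa")
  set.seed(pg_seed(seed))

  taxa <- c("focal_sp", sprintf("sp_%04d", seq_len(n_taxa - 1)))
  pos_ids <- taxa[1 + seq_len(n_planted_positive)]
  neg_ids <- taxa[1 + n_planted_positive + seq_len(n_planted_negative)]

  s <- association_strength
  z_focal <- rnorm(n_samples)
  Z <- matrix(rnorm(n_samples * n_taxa), n_samples, n_taxa,
              dimnames = list(sprintf("sample_%05d", seq_len(n_samples)), taxa))
  Z[, 1] <- z_focal
  sgn <- c(rep(1, n_planted_positive), rep(-1, n_planted_negative))
  for (j in seq_len(n_planted))
    Z[, 1 + j] <- sgn[j] * s * z_focal + sqrt(1 - s^2) * Z[, 1 + j]

  meanlog <- rnorm(n_taxa, -1, 1)
  sdlog <- runif(n_taxa, 0.5, 1.5)
  zi <- rep_len(zero_inflation, n_taxa)
  zi[1] <- focal_zero_inflation
  ab <- sapply(seq_len(n_taxa), function(j) {
    x <- qlnorm(pnorm(Z[, j]), meanlog[j], sdlog[j])
    if (zi[j] >= 1) return(rep(0, n_samples))
    x[x < qlnorm(zi[j], meanlog[j], sdlog[j])] <- 0
    x
  })
  dimnames(ab) <- dimnames(Z)
  # Percent of a fixed community size covering the profiled taxa plus an
  # unprofiled remainder.  A global constant denominator is a monotone
  # per-taxon transform, so the planted copula (and hence every Spearman
  # rank statistic) is preserved exactly; per-sample closure would
  # distort it.
  expected_total <- sum(exp(meanlog + sdlog^2 / 2) * (1 - zi))
  denom <- max((1 + unclassified_weight) * max(expected_total, 1e-9),
               max(rowSums(ab)))
  ab <- ab / denom * 100

  metadata <- data.frame(
    sample_id = rownames(ab),
    region = rep(names(regions), times = regions)[sample.int(n_samples)],
    stringsAsFactors = FALSE)
  metadata$age_class <- if (is.null(age_classes)) NA_character_ else
    sample(age_classes, n_samples, replace = TRUE)

  list(abundance = ab, metadata = metadata,
       truth = list(focal = "focal_sp", positive = pos_ids,
                    negative = neg_ids,
                    association_strength = association_strength),
       params = list(n_samples = n_samples, n_taxa = n_taxa,
                     zero_inflation = zero_inflation, regions = regions,
                     seed = seed))
}
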