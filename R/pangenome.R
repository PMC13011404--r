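# Pangenome partitioning, permutation-averaged accumulation curves,
# Heaps'-law openness fitting, and species-specific soft-core detection.

#' Partition a pangenome by gene-family prevalence
#'
#' Prevalence is the exact fraction of genomes carrying a family (integer
#' column sums divided by genome count).  Boundary convention: a family
#' exactly at `core_min` is core, exactly at `soft_min` is soft-core,
#' exactly at `cloud_max` is shell.
#'
#' @param matrix genomes x families binary matrix.
#' @param core_min,soft_min,cloud_max prevalence thresholds with
#'   `0 < cloud_max < soft_min < core_min <= 1`.
#' @return List of class `pangenome_partition` with family-id sets
#'   `core`, `soft_core`, `shell`, `cloud`, the per-family `prevalence`
#'   vector, and the thresholds used.
#' @export
partition_pangenome <- function(matrix, core_min = 0.99, soft_min = 0.95,
                                cloud_max = 0.15) {
  matrix <- validate_pa_matrix(matrix)
  if (!(cloud_max > 0 && cloud_max < soft_min && soft_min < core_min &&
        core_min <= 1))
    pg_stop("thresholds must satisfy 0 < cloud_max < soft_min < core_min <= 1")
  prev <- colSums(matrix) / nrow(matrix)
  cls <- ifelse(prev >= core_min, "core",
         ifelse(prev >= soft_min, "soft_core",
         ifelse(prev >= cloud_max, "shell", "cloud")))
  structure(list(
    core = colnames(matrix)[cls == "core"],
    soft_core = colnames(matrix)[cls == "soft_core"],
    shell = colnames(matrix)[cls == "shell"],
    cloud = colnames(matrix)[cls == "cloud"],
    prevalence = prev, class = cls,
    thresholds = c(core_min = core_min, soft_min = soft_min,
                   cloud_max = cloud_max)),
    class = "pangenome_partition")
}

#' Permutation-averaged gene accumulation curves
#'
#' For each of `n_permutations` random genome orders, records the number
#' of novel gene families contributed at every addition step and the
#' cumulative pangenome size; returns means and standard deviations
#' across permutations.
#'
#' @param matrix genomes x families binary matrix.
#' @param n_permutations number of random genome orders (default 1000).
#' @param seed integer seed.
#' @return List of class `accumulation_curves` with `mean_pangenome_size`,
#'   `sd_pangenome_size`, `mean_new_genes`, `sd_new_genes` (length =
#'   genome count), `n_permutations` and `seed`.
#' @export
accumulation_curves <- function(matrix, n_permutations = 1000, seed = NULL) {
  matrix <- validate_pa_matrix(matrix)
  if (n_permutations < 1) pg_stop("n_permutations must be >= 1")
  set.seed(pg_seed(seed))
  G <- nrow(matrix)
  orders <- t(vapply(seq_len(n_permutations), function(i) sample.int(G),
                     integer(G)))
  new_mat <- .accum_new_genes(matrix, orders)
  cum_mat <- t(apply(new_mat, 1, cumsum))
  if (G == 1) cum_mat <- t(cum_mat)
  structure(list(
    n_permutations = n_permutations,
    mean_pangenome_size = colMeans(cum_mat),
    sd_pangenome_size = apply(cum_mat, 2, sd),
    mean_new_genes = colMeans(new_mat),
    sd_new_genes = apply(new_mat, 2, sd),
    seed = seed), class = "accumulation_curves")
}

#' Fit Heaps' law to an accumulation curve
#'
#' Ordinary least squares of `log(mean_new_genes[N])` on `log(N)` over
#' the usable points (the first `skip_first` points and any zero values
#' are excluded: the first genome contributes its whole gene complement,
#' not a discovery-law point, and `log(0)` is undefined).  The decay
#' exponent is `alpha = -slope`, the scale `kappa = exp(intercept)`, and
#' the pangenome is called closed iff `alpha > 1`.
#'
#' @param curves an `accumulation_curves` object, or a numeric vector of
#'   mean new-gene counts per addition step.
#' @param skip_first leading points to drop (default 1).
#' @return List of class `heaps_fit` with `kappa`, `alpha`, `r_squared`,
#'   `verdict` (`"open"`/`"closed"`) and `n_points`.
#' @export
fit_heaps <- function(curves, skip_first = 1) {
  mn <- if (inherits(curves, "accumulation_curves")) curves$mean_new_genes
        else as.numeric(curves)
  N <- seq_along(mn)
  use <- N > skip_first & mn > 0
  if (sum(use) < 3) pg_stop("curve too short or saturated: %d usable points",
                            sum(use))
  fit <- lm(log(mn[use]) ~ log(N[use]))
  alpha <- -unname(coef(fit)[2])
  structure(list(
    kappa = exp(unname(coef(fit)[1])),
    alpha = alpha,
    # summary.lm warns on numerically perfect fits (exact power laws)
    r_squared = suppressWarnings(summary(fit)$r.squared),
    verdict = if (alpha > 1) "closed" else "open",
    n_points = sum(use)), class = "heaps_fit")
}

#' Gene families specific to one species' soft-core
#'
#' From a multi-species presence/absence matrix, returns the families
#' with prevalence at least `soft_min` among the focal species' genomes
#' and at most `other_max` within every other species.
#'
#' @param multi_matrix genomes x families binary matrix spanning several
#'   species.
#' @param species_labels per-genome species label (ordered as the matrix
#'   rows).
#' @param focal focal species label.
#' @param soft_min minimum focal prevalence (default 0.95).
#' @param other_max maximum prevalence allowed in each other species
#'   (default 0, i.e. exclusive presence).
#' @return Character vector of family ids.
#' @export
find_species_specific_cogs <- function(multi_matrix, species_labels, focal,
                                       soft_min = 0.95, other_max = 0) {
  multi_matrix <- validate_pa_matrix(multi_matrix)
  if (length(species_labels) != nrow(multi_matrix))
    pg_stop("species_labels must match matrix rows")
  if (!focal %in% species_labels)
    pg_stop("focal species '%s' has no genomes", focal)
  tab <- table(species_labels)
  if (any(tab == 0)) pg_stop("species with zero genomes")
  prev_by_sp <- rowsum(multi_matrix, species_labels)
  prev_by_sp <- prev_by_sp / as.vector(tab[rownames(prev_by_sp)])
  focal_prev <- prev_by_sp[focal, ]
  others <- prev_by_sp[setdiff(rownames(prev_by_sp), focal), , drop = FALSE]
  keep <- focal_prev >= soft_min &
    (nrow(others) == 0 | apply(others <= other_max, 2, all))
  colnames(multi_matrix)[keep]
}
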