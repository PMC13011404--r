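# Genome clustering: 1 - gANI and Jaccard distances, group-average HCA
# with elbow-method k selection, PCoA, a permutation test for per-gene
# influence on the ordination, and cluster-metadata enrichment.

#' Convert a gANI identity matrix to a distance matrix
#'
#' Accepts identities on a 0-1 or 0-100 (percent) scale, normalises
#' percent input to fractions, and returns `1 - gANI` with a zero
#' diagonal.  Distances are used as-is downstream (no re-normalisation).
#'
#' @param gani square symmetric identity matrix with self-identity on the
#'   diagonal.
#' @return Square distance matrix.
#' @export
ani_to_distance <- function(gani) {
  if (nrow(gani) != ncol(gani)) pg_stop("gANI matrix must be square")
  if (max(abs(gani - t(gani))) > 1e-6)
    pg_stop("gANI matrix asymmetric beyond 1e-6")
  if (max(gani) > 1.5) gani <- gani / 100      # percent scale
  d <- 1 - gani
  diag(d) <- 0
  if (any(d < -1e-9)) pg_stop("identities above the identity-scale maximum")
  d[d < 0] <- 0
  d
}

#' Jaccard distance between genome gene sets
#'
#' `d(i, j) = 1 - |intersection| / |union|` of the gene-family sets of
#' genomes `i` and `j`; 0 when both sets are empty.
#'
#' @param matrix genomes x families binary matrix.
#' @return Square distance matrix over genomes.
#' @export
jaccard_distance <- function(matrix) {
  matrix <- validate_pa_matrix(matrix)
  m <- matrix * 1.0
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- ifelse(uni > 0, 1 - inter / uni, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(matrix), rownames(matrix))
  d
}

#' Group-average hierarchical clustering with elbow k selection
#'
#' UPGMA (group-average) agglomeration on a precomputed distance matrix,
#' without re-standardisation.  For each candidate `k` the tree is cut
#' and the intra-cluster sum of squares computed as the sum over clusters
#' of squared distances to the cluster medoid; if `k` is not supplied it
#' is chosen by [choose_k_elbow()].
#'
#' @param dist square distance matrix.
#' @param k_max largest candidate cluster count (`2 <= k_max < n`).
#' @param k optional fixed cluster count.
#' @return List of class `clustering_result`: `k`, `labels` (named, in
#'   `1..k`), `wcss_curve` (k = 1..k_max), `linkage`, and the `hclust`
#'   object.
#' @export
hca_cluster <- function(dist, k_max = 10, k = NULL) {
  n <- nrow(dist)
  if (!is.null(k) && k > n) pg_stop("k (%d) exceeds item count (%d)", k, n)
  if (k_max < 2 || k_max >= n)
    pg_stop("k_max must satisfy 2 <= k_max < n items")
  hc <- stats::hclust(stats::as.dist(dist), method = "average")
  wcss <- vapply(seq_len(k_max), function(kk) {
    labels <- stats::cutree(hc, k = kk)
    sum(vapply(split(seq_len(n), labels), function(idx) {
      if (length(idx) == 1) return(0)
      sub2 <- dist[idx, idx, drop = FALSE]^2
      min(colSums(sub2))                      # squared distances to medoid
    }, 0))
  }, 0)
  if (is.null(k)) k <- choose_k_elbow(wcss)
  labels <- stats::cutree(hc, k = k)
  structure(list(k = k, labels = labels, wcss_curve = wcss,
                 linkage = "average", hclust = hc),
            class = "clustering_result")
}

#' Elbow-method choice of cluster count
#'
#' Returns the interior `k` (2..k_max-1) maximising the perpendicular
#' distance from `(k, WCSS_k)` to the chord joining `(1, WCSS_1)` and
#' `(k_max, WCSS_k_max)`; ties break toward smaller `k`.
#'
#' @param wcss_curve non-increasing WCSS values for k = 1..k_max
#'   (length >= 3).
#' @return The chosen `k`.
#' @export
choose_k_elbow <- function(wcss_curve) {
  m <- length(wcss_curve)
  if (m < 3) pg_stop("wcss curve must have length >= 3")
  if (any(diff(wcss_curve) > 1e-9 * max(abs(wcss_curve), 1)))
    pg_stop("wcss curve must be non-increasing")
  x1 <- 1; y1 <- wcss_curve[1]; x2 <- m; y2 <- wcss_curve[m]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  k_int <- 2:(m - 1)
  d <- abs((y2 - y1) * k_int - (x2 - x1) * wcss_curve[k_int] +
             x2 * y1 - y2 * x1) / len
  k_int[which.max(d)]                        # which.max ties -> smaller k
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres `-d^2/2`, eigendecomposes, and scales eigenvectors by
#' the square root of their (positive) eigenvalues.  Negative eigenvalues
#' are dropped from the variance-explained denominator and logged.
#'
#' @param dist square distance matrix.
#' @param n_axes number of axes to retain (default 3; reduced with a
#'   warning if fewer positive eigenvalues exist).
#' @return List of class `pcoa_result`: `coordinates` (items x axes),
#'   `eigenvalues` (all, descending), `variance_explained` (per retained
#'   axis, over positive eigenvalue mass), `n_negative`.
#' @export
pcoa <- function(dist, n_axes = 3) {
  if (n_axes < 2) pg_stop("n_axes must be >= 2")
  n <- nrow(dist)
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(dist), k = n - 1,
                                         eig = TRUE))
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- which(sc$eig > 1e-12 * max(abs(sc$eig)))
  if (length(pos) < n_axes) {
    pg_warn("only %d positive eigenvalues; returning %d axes instead of %d",
            length(pos), length(pos), n_axes)
    n_axes <- length(pos)
  }
  n_neg <- sum(sc$eig < -1e-12 * max(abs(sc$eig)))
  if (n_neg > 0)
    pg_log("%d negative eigenvalues dropped from variance denominator", n_neg)
  coords <- sc$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- sprintf("axis_%d", seq_len(n_axes))
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    variance_explained = eig[seq_len(n_axes)] / sum(eig[eig > 0]),
    n_negative = n_neg), class = "pcoa_result")
}

#' Permutation test for per-gene influence on PCoA axes
#'
#' For each variable gene family and each axis, the observed statistic is
#' the difference between the mean axis coordinate of carrier genomes and
#' that of non-carriers.  The null is built by shuffling the family's
#' presence labels across genomes `n_permutations` times;
#' `z = (obs - null mean) / null sd`, with a two-sided normal p-value on
#' `z`.  Benjamini-Hochberg correction is applied across all gene x axis
#' tests; a family is flagged overall if significant on any axis.
#'
#' Implementation note: permutations are realised through one pool of
#' random genome orders shared across families — the first `k` elements
#' of a random order are a uniform `k`-subset, so each family's null is
#' exactly its own label-shuffling null.
#'
#' @param pcoa a `pcoa_result` whose rows align with `matrix` rows.
#' @param matrix genomes x families binary matrix.
#' @param n_permutations permutation count (>= 100).
#' @param seed integer seed.
#' @return Data frame (`cog_id`, `axis`, `z_score`, `p_value`, `p_bh`,
#'   `significant`) with attribute `significant_genes` (families
#'   significant on any axis).  Constant families are skipped.
#' @export
gene_influence <- function(pcoa, matrix, n_permutations = 1000, seed = NULL) {
  if (n_permutations < 100)
    pg_stop("n_permutations must be >= 100 (unstable null below that)")
  matrix <- validate_pa_matrix(matrix)
  A <- pcoa$coordinates
  if (nrow(A) != nrow(matrix))
    pg_stop("matrix rows (%d) do not align with pcoa coordinates (%d)",
            nrow(matrix), nrow(A))
  n <- nrow(A); nax <- ncol(A)
  kvec <- colSums(matrix)
  variable <- kvec > 0 & kvec < n
  if (any(!variable))
    pg_log("skipping %d constant gene families", sum(!variable))
  M <- matrix[, variable, drop = FALSE]
  kvec <- kvec[variable]
  set.seed(pg_seed(seed))

  # cumulative sums of permuted coordinates: CS[r, k, ax] is the sum of
  # axis ax over a uniform k-subset of genomes (permutation r)
  R <- n_permutations
  cs <- array(0, c(R, n, nax))
  for (r in seq_len(R)) cs[r, , ] <- apply(A[sample.int(n), , drop = FALSE],
                                           2, cumsum)
  null_mean <- apply(cs, c(2, 3), mean)      # n x nax
  null_sd <- apply(cs, c(2, 3), sd)
  tot <- colSums(A)

  obs_sum <- t(M) %*% A                      # families x axes carrier sums
  res <- vector("list", nax)
  for (ax in seq_len(nax)) {
    a <- 1 / kvec + 1 / (n - kvec)           # affine map subset-sum -> stat
    b <- tot[ax] / (n - kvec)
    obs <- obs_sum[, ax] * a - b
    mu <- null_mean[kvec, ax] * a - b
    sdv <- null_sd[kvec, ax] * a
    z <- (obs - mu) / sdv
    res[[ax]] <- data.frame(cog_id = colnames(M), axis = ax,
                            z_score = z, p_value = 2 * pnorm(-abs(z)),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  out$p_bh <- bh_adjust(out$p_value)
  out$significant <- out$p_bh < 0.05
  attr(out, "significant_genes") <- unique(out$cog_id[out$significant])
  out
}

#' Cluster-metadata enrichment by Fisher's exact test
#'
#' One-vs-rest 2x2 Fisher exact test (two-sided) for every pair of levels
#' of two categorical labelings, with Benjamini-Hochberg correction
#' across all pairs.  Significance uses the dual threshold
#' `p < 1e-5 AND p_bh < 0.05`.  Levels covering zero or all items are
#' excluded with a warning.
#'
#' @param labels,groups equal-length categorical vectors over the same
#'   items (e.g. cluster assignment and geographic region).
#' @return Data frame (`label_level`, `group_level`, `n_overlap`,
#'   `odds_ratio`, `p_value`, `p_bh`, `significant`).
#' @export
categorical_enrichment <- function(labels, groups) {
  if (length(labels) != length(groups))
    pg_stop("labels and groups must cover the same items")
  n <- length(labels)
  keep_level <- function(v) {
    tab <- table(v)
    bad <- names(tab)[tab == 0 | tab == n]
    if (length(bad) > 0)
      pg_warn("excluding level(s) covering zero or all items: %s",
              paste(bad, collapse = ", "))
    setdiff(names(tab), bad)
  }
  la <- keep_level(labels); gb <- keep_level(groups)
  if (length(la) == 0 || length(gb) == 0)
    pg_stop("no testable level pairs")
  rows <- list()
  for (a in la) for (b in gb) {
    t11 <- sum(labels == a & groups == b)
    t12 <- sum(labels == a & groups != b)
    t21 <- sum(labels != a & groups == b)
    t22 <- sum(labels != a & groups != b)
    ft <- fisher.test(matrix(c(t11, t21, t12, t22), 2))
    rows[[length(rows) + 1]] <- data.frame(
      label_level = a, group_level = b, n_overlap = t11,
      odds_ratio = unname(ft$estimate), p_value = ft$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p_value)
  out$significant <- out$p_value < 1e-5 & out$p_bh < 0.05
  out
}
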