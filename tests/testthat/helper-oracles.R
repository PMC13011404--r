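# Independent oracles used across the suite: brute-force enumerations
# and closed forms kept deliberately separate from the package's own
# code paths.

options(pangloss.quiet = TRUE)

# exact permutation expectation of accumulation curves by enumerating
# every genome order (feasible for <= 6 genomes)
enum_accumulation <- function(m) {
  G <- nrow(m)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  sizes <- matrix(0, 0, G); news <- matrix(0, 0, G)
  for (ord in perms(seq_len(G))) {
    seen <- rep(FALSE, ncol(m))
    nn <- numeric(G)
    for (j in seq_len(G)) {
      idx <- which(m[ord[j], ] == 1)
      nn[j] <- sum(!seen[idx])
      seen[idx] <- TRUE
    }
    news <- rbind(news, nn)
    sizes <- rbind(sizes, cumsum(nn))
  }
  list(mean_new = colMeans(news), mean_size = colMeans(sizes))
}

# exhaustive minimum Wagner cost over all internal-state assignments
# (vectorised across the 2^n_internal assignments)
brute_wagner_cost <- function(tree, states, gain_cost = 2, loss_cost = 1,
                              root_origin = TRUE) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  root <- ntip + 1
  x <- states[tree$tip.label]
  nmask <- 2^nint
  bits <- matrix(0L, nint, nmask)
  for (i in seq_len(nint))
    bits[i, ] <- rep(rep(0:1, each = 2^(i - 1)), length.out = nmask)
  assign <- rbind(matrix(x, ntip, nmask), bits)
  cost <- numeric(nmask)
  for (e in seq_len(nrow(tree$edge))) {
    sp <- assign[tree$edge[e, 1], ]; sc <- assign[tree$edge[e, 2], ]
    cost <- cost + gain_cost * (sp == 0 & sc == 1) +
      loss_cost * (sp == 1 & sc == 0)
  }
  if (root_origin) cost <- cost + gain_cost * (assign[root, ] == 1)
  min(cost)
}

# Spearman rho by direct average-rank arithmetic
rank_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Benjamini-Hochberg step-up straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  run <- Inf
  for (i in rev(seq_len(m))) {
    run <- min(run, m * p[o[i]] / i)
    q[o[i]] <- min(1, run)
  }
  q
}

# tiny deterministic presence/absence fixture
toy_matrix <- function() {
  m <- rbind(
    g1 = c(1, 1, 0, 0),
    g2 = c(0, 1, 1, 0),
    g3 = c(0, 0, 1, 1))
  colnames(m) <- letters[1:4]
  storage.mode(m) <- "integer"
  m
}
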