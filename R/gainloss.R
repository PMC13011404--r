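# Asymmetric-cost Wagner parsimony for binary gene families on a rooted
# tree (Sankoff dynamic programming, gain cost 2 / loss cost 1 by
# default), with a root-origin convention, permutation significance and
# lineage-level gain/loss classification.

# Vectorised binary Sankoff over many characters at once.
# X: tips x characters 0/1 matrix (rows ordered as tree$tip.label).
# Returns min cost, gains, losses, root state and per-edge event
# matrices (rows ordered as tree$edge).
# Tie-breaks: minimise (cost, gains) lexicographically, then prefer
# absence.  Root presence is charged one extra gain when root_origin.
sankoff_binary <- function(tree, X, gain_cost = 2, loss_cost = 1,
                           root_origin = TRUE) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  C <- ncol(X)
  BIG <- 1e12
  post <- ape::reorder.phylo(tree, "postorder")
  pe <- post$edge
  root <- ntip + 1L

  # DP tables: cost and (secondary objective) gains per node and state
  cost0 <- matrix(0, ntip + nnode, C); cost1 <- matrix(0, ntip + nnode, C)
  gain0 <- matrix(0, ntip + nnode, C); gain1 <- matrix(0, ntip + nnode, C)
  cost0[seq_len(ntip), ] <- ifelse(X == 0L, 0, BIG)
  cost1[seq_len(ntip), ] <- ifelse(X == 1L, 0, BIG)

  # lexicographic min of (cost, gains); tie -> prefer state 0 option
  for (e in seq_len(nrow(pe))) {
    p <- pe[e, 1]; ch <- pe[e, 2]
    for (s in 0:1) {
      c_opt0 <- cost0[ch, ] + if (s == 1) loss_cost else 0
      g_opt0 <- gain0[ch, ]
      c_opt1 <- cost1[ch, ] + if (s == 0) gain_cost else 0
      g_opt1 <- gain1[ch, ] + if (s == 0) 1 else 0
      take1 <- c_opt1 < c_opt0 | (c_opt1 == c_opt0 & g_opt1 < g_opt0)
      cc <- ifelse(take1, c_opt1, c_opt0)
      gg <- ifelse(take1, g_opt1, g_opt0)
      if (s == 0) { cost0[p, ] <- cost0[p, ] + cc; gain0[p, ] <- gain0[p, ] + gg }
      else        { cost1[p, ] <- cost1[p, ] + cc; gain1[p, ] <- gain1[p, ] + gg }
    }
  }

  rc0 <- cost0[root, ]; rg0 <- gain0[root, ]
  rc1 <- cost1[root, ] + if (root_origin) gain_cost else 0
  rg1 <- gain1[root, ] + if (root_origin) 1 else 0
  root_present <- rc1 < rc0 | (rc1 == rc0 & rg1 < rg0)
  min_cost <- ifelse(root_present, rc1, rc0)

  # traceback in preorder (reverse postorder)
  states <- matrix(NA_integer_, ntip + nnode, C)
  states[root, ] <- as.integer(root_present)
  gain_edge <- matrix(0L, nrow(tree$edge), C)
  loss_edge <- matrix(0L, nrow(tree$edge), C)
  edge_row <- match(pe[, 2], tree$edge[, 2])
  for (e in rev(seq_len(nrow(pe)))) {
    p <- pe[e, 1]; ch <- pe[e, 2]
    sp <- states[p, ]
    c_opt0 <- cost0[ch, ] + ifelse(sp == 1L, loss_cost, 0)
    g_opt0 <- gain0[ch, ]
    c_opt1 <- cost1[ch, ] + ifelse(sp == 0L, gain_cost, 0)
    g_opt1 <- gain1[ch, ] + ifelse(sp == 0L, 1, 0)
    take1 <- c_opt1 < c_opt0 | (c_opt1 == c_opt0 & g_opt1 < g_opt0)
    sc <- as.integer(take1)
    states[ch, ] <- sc
    er <- edge_row[e]
    gain_edge[er, ] <- as.integer(sp == 0L & sc == 1L)
    loss_edge[er, ] <- as.integer(sp == 1L & sc == 0L)
  }

  gains <- colSums(gain_edge) + if (root_origin) as.integer(root_present) else 0L
  losses <- colSums(loss_edge)
  list(min_cost = min_cost, gains = gains, losses = losses,
       root_state = ifelse(root_present, "present", "absent"),
       gain_edge = gain_edge, loss_edge = loss_edge,
       node_states = states)
}

#' Wagner parsimony gain/loss events for one gene family
#'
#' Sankoff dynamic programming with transition costs
#' `c(0 -> 1) = gain_cost`, `c(1 -> 0) = loss_cost`, `c(s -> s) = 0` on a
#' rooted tree.  A root resolved present is charged one additional gain
#' (virtual origin-from-absence convention), so that the gain penalty
#' acts on origins as well; disable with `root_origin = FALSE`.  Among
#' co-optimal reconstructions the traceback deterministically prefers
#' fewer gains, then absence.
#'
#' @param tree rooted `phylo`.
#' @param presence named 0/1 vector over the tips.
#' @param gain_cost,loss_cost positive transition costs (defaults 2, 1).
#' @param root_origin charge a gain for presence at the root (default
#'   TRUE).
#' @return List of class `gainloss_events`: `min_cost`, `gains`,
#'   `losses`, `root_state`, and `per_branch` (data frame of events with
#'   parent/child node ids and tip labels where applicable).
#' @export
wagner_events <- function(tree, presence, gain_cost = 2, loss_cost = 1,
                          root_origin = TRUE) {
  if (!ape::is.rooted(tree))
    pg_stop("tree is unrooted; root it before gain/loss inference")
  stopifnot(gain_cost > 0, loss_cost > 0)
  miss <- setdiff(tree$tip.label, names(presence))
  if (length(miss) > 0)
    pg_stop("tips without a state: %s", paste(miss, collapse = ", "))
  x <- as.integer(presence[tree$tip.label])
  if (!all(x %in% 0:1)) pg_stop("presence states must be 0/1")
  r <- sankoff_binary(tree, matrix(x, ncol = 1), gain_cost, loss_cost,
                      root_origin)
  ev <- which(r$gain_edge[, 1] == 1L | r$loss_edge[, 1] == 1L)
  lab <- c(tree$tip.label, rep(NA, tree$Nnode))
  per_branch <- data.frame(
    parent = tree$edge[ev, 1], child = tree$edge[ev, 2],
    child_label = lab[tree$edge[ev, 2]],
    event = ifelse(r$gain_edge[ev, 1] == 1L, "gain", "loss"),
    stringsAsFactors = FALSE)
  structure(list(min_cost = r$min_cost[1], gains = r$gains[1],
                 losses = r$losses[1], root_state = r$root_state[1],
                 per_branch = per_branch,
                 costs = c(gain = gain_cost, loss = loss_cost),
                 root_origin = root_origin),
            class = "gainloss_events")
}

#' Gain/loss events for every family of a presence/absence matrix
#'
#' Applies Wagner parsimony per gene family; identical presence patterns
#' are computed once and shared (pattern memoisation).
#'
#' @param tree rooted `phylo` whose tips equal the matrix genomes.
#' @param matrix genomes x families binary matrix.
#' @param gain_cost,loss_cost,root_origin see [wagner_events()].
#' @return List with `summary` (data frame: `cog_id`, `gains`, `losses`,
#'   `min_cost`, `root_state`) and `gain_edge` / `loss_edge` event
#'   matrices (rows ordered as `tree$edge`, columns = families).
#' @export
pangenome_events <- function(tree, matrix, gain_cost = 2, loss_cost = 1,
                             root_origin = TRUE) {
  matrix <- validate_pa_matrix(matrix)
  extra_tips <- setdiff(tree$tip.label, rownames(matrix))
  extra_gen <- setdiff(rownames(matrix), tree$tip.label)
  if (length(extra_tips) > 0 || length(extra_gen) > 0)
    pg_stop("tip set and genome set differ (tips not in matrix: %s; genomes not in tree: %s)",
            paste(c(extra_tips, "-")[1], collapse = ","),
            paste(c(extra_gen, "-")[1], collapse = ","))
  X <- t(matrix[tree$tip.label, , drop = FALSE]) # families x tips
  key <- apply(X, 1, paste, collapse = "")
  uniq <- !duplicated(key)
  map <- match(key, key[uniq])
  r <- sankoff_binary(tree, t(X[uniq, , drop = FALSE]), gain_cost,
                      loss_cost, root_origin)
  summary <- data.frame(
    cog_id = colnames(matrix),
    gains = r$gains[map], losses = r$losses[map],
    min_cost = r$min_cost[map], root_state = r$root_state[map],
    stringsAsFactors = FALSE)
  list(summary = summary,
       gain_edge = r$gain_edge[, map, drop = FALSE],
       loss_edge = r$loss_edge[, map, drop = FALSE])
}

#' Permutation significance and stability of gain/loss events
#'
#' For each family the null is built by shuffling its tip states across
#' tips `n_label_perms` times and recomputing gains and losses.  Each
#' tail gets a z-score and a two-sided empirical p-value with +1
#' smoothing (`p = (1 + #null-as-extreme) / (1 + n)` per tail, doubled
#' and capped at 1), Benjamini-Hochberg corrected across families per
#' tail.  Stability is the fraction of subsample rounds (random subsets
#' of tips, induced subtree) reproducing the family's class.  The final
#' class uses the dual threshold `p < 1e-5 AND FDR < 0.05`; when
#' `n_label_perms` cannot resolve 1e-5 the p-threshold falls back to the
#' smallest attainable value with a logged warning.
#'
#' @param tree rooted `phylo`.
#' @param matrix genomes x families binary matrix.
#' @param n_label_perms label permutations (>= 100).
#' @param n_subsample_rounds subsample rounds for stability (0 disables).
#' @param subsample_frac fraction of tips kept per round.
#' @param round_perms permutations used inside each stability round.
#' @param gain_cost,loss_cost,root_origin see [wagner_events()].
#' @param seed integer seed.
#' @return Data frame (`cog_id`, `gains`, `losses`, `z_gain`, `z_loss`,
#'   `p_gain`, `p_loss`, `fdr_gain`, `fdr_loss`, `class`, `stability`).
#' @export
event_significance <- function(tree, matrix, n_label_perms = 1000,
                               n_subsample_rounds = 100,
                               subsample_frac = 0.8, round_perms = 200,
                               gain_cost = 2, loss_cost = 1,
                               root_origin = TRUE, seed = NULL) {
  if (n_label_perms < 100) pg_stop("n_label_perms must be >= 100")
  matrix <- validate_pa_matrix(matrix)
  set.seed(pg_seed(seed))
  p_crit <- 1e-5
  min_attainable <- 2 / (1 + n_label_perms)
  if (min_attainable > p_crit) {
    p_crit <- min_attainable
    pg_log("n_label_perms = %d cannot resolve p < 1e-5; using smallest attainable threshold %.3g",
           n_label_perms, p_crit)
  }

  obs <- pangenome_events(tree, matrix, gain_cost, loss_cost, root_origin)
  ntip <- nrow(matrix)
  # a class requires an EXCESS of events over the shuffled null (upper
  # direction), not merely a two-sided departure: phylogenetically
  # clustered families have fewer events than shuffled labels, which is
  # conservation, not gain/loss signal
  classify <- function(pg_, fg_, zg_, pl_, fl_, zl_) {
    g_sig <- pg_ <= p_crit & fg_ < 0.05 & zg_ > 0
    l_sig <- pl_ <= p_crit & fl_ < 0.05 & zl_ > 0
    ifelse(g_sig & l_sig, "both",
           ifelse(g_sig, "GoF", ifelse(l_sig, "LoF", "none")))
  }

  one_cog_null <- function(x, R) {
    perms <- vapply(seq_len(R), function(i) x[sample.int(ntip)],
                    integer(ntip))
    r <- sankoff_binary(tree, perms, gain_cost, loss_cost, root_origin)
    list(gains = r$gains, losses = r$losses)
  }

  C <- ncol(matrix)
  z_gain <- z_loss <- p_gain <- p_loss <- numeric(C)
  for (j in seq_len(C)) {
    nul <- one_cog_null(matrix[, j], n_label_perms)
    og <- obs$summary$gains[j]; ol <- obs$summary$losses[j]
    two_sided <- function(null_v, o) {
      up <- (1 + sum(null_v >= o)) / (1 + n_label_perms)
      dn <- (1 + sum(null_v <= o)) / (1 + n_label_perms)
      min(1, 2 * min(up, dn))
    }
    sg <- sd(nul$gains); sl <- sd(nul$losses)
    z_gain[j] <- if (sg > 0) (og - mean(nul$gains)) / sg else 0
    z_loss[j] <- if (sl > 0) (ol - mean(nul$losses)) / sl else 0
    p_gain[j] <- two_sided(nul$gains, og)
    p_loss[j] <- two_sided(nul$losses, ol)
    # a constant family has a degenerate null identical to the observed
    if (sg == 0 && og == mean(nul$gains)) p_gain[j] <- 1
    if (sl == 0 && ol == mean(nul$losses)) p_loss[j] <- 1
  }
  fdr_gain <- bh_adjust(p_gain)
  fdr_loss <- bh_adjust(p_loss)
  cls <- classify(p_gain, fdr_gain, z_gain, p_loss, fdr_loss, z_loss)

  stability <- rep(NA_real_, C)
  if (n_subsample_rounds > 0) {
    round_crit <- max(1e-5, 2 / (1 + round_perms))
    hits <- matrix(0, n_subsample_rounds, C)
    ok_rounds <- logical(n_subsample_rounds)
    for (r in seq_len(n_subsample_rounds)) {
      keep <- sort(sample.int(ntip, max(2, round(subsample_frac * ntip))))
      if (length(keep) < 4) {
        pg_warn("subsample round %d leaves < 4 tips; skipped", r)
        next
      }
      ok_rounds[r] <- TRUE
      sub_tree <- ape::keep.tip(tree, rownames(matrix)[keep])
      sub_m <- matrix[sub_tree$tip.label, , drop = FALSE]
      sub_obs <- pangenome_events(sub_tree, validate_pa_matrix(sub_m),
                                  gain_cost, loss_cost, root_origin)
      kept_cols <- match(sub_obs$summary$cog_id, colnames(matrix))
      pgv <- plv <- rep(1, C)
      zgv <- zlv <- rep(0, C)
      for (jj in seq_along(kept_cols)) {
        j <- kept_cols[jj]
        x <- sub_m[, sub_obs$summary$cog_id[jj]]
        perms <- vapply(seq_len(round_perms),
                        function(i) x[sample.int(length(x))],
                        integer(length(x)))
        rr <- sankoff_binary(sub_tree, perms, gain_cost, loss_cost,
                             root_origin)
        og <- sub_obs$summary$gains[jj]; ol <- sub_obs$summary$losses[jj]
        up <- (1 + sum(rr$gains >= og)) / (1 + round_perms)
        dn <- (1 + sum(rr$gains <= og)) / (1 + round_perms)
        pgv[j] <- min(1, 2 * min(up, dn))
        zgv[j] <- og - mean(rr$gains)
        if (sd(rr$gains) == 0 && og == mean(rr$gains)) pgv[j] <- 1
        up <- (1 + sum(rr$losses >= ol)) / (1 + round_perms)
        dn <- (1 + sum(rr$losses <= ol)) / (1 + round_perms)
        plv[j] <- min(1, 2 * min(up, dn))
        zlv[j] <- ol - mean(rr$losses)
        if (sd(rr$losses) == 0 && ol == mean(rr$losses)) plv[j] <- 1
      }
      fg <- bh_adjust(pgv); fl <- bh_adjust(plv)
      g_sig <- pgv <= round_crit & fg < 0.05 & zgv > 0
      l_sig <- plv <= round_crit & fl < 0.05 & zlv > 0
      round_cls <- ifelse(g_sig & l_sig, "both",
                          ifelse(g_sig, "GoF", ifelse(l_sig, "LoF", "none")))
      hits[r, ] <- round_cls == cls
    }
    if (any(ok_rounds))
      stability <- colMeans(hits[ok_rounds, , drop = FALSE])
  }

  data.frame(cog_id = colnames(matrix),
             gains = obs$summary$gains, losses = obs$summary$losses,
             z_gain = z_gain, z_loss = z_loss,
             p_gain = p_gain, p_loss = p_loss,
             fdr_gain = fdr_gain, fdr_loss = fdr_loss,
             class = cls, stability = stability,
             stringsAsFactors = FALSE)
}

#' Classify lineage-specific gain/loss candidates
#'
#' A lineage gain-of-function candidate is a family in the focal
#' species' soft-core whose prevalence is below `cloud_max` in every
#' sibling species; a lineage loss-of-function candidate is a family in
#' the focal cloud that is highly conserved (prevalence at least
#' `conserved_min`) in at least one sibling.
#'
#' @param focal_partition `pangenome_partition` of the focal species.
#' @param sibling_prevalence families x sibling-species matrix of
#'   prevalences (shared family ids).
#' @param soft_min,cloud_max,conserved_min thresholds (defaults 0.95,
#'   0.15, 0.90).
#' @param significance optional [event_significance()] result merged in.
#' @return Data frame (`cog_id`, `lineage_class` in
#'   `{GoF_candidate, LoF_candidate, none}`, plus `event_class` when
#'   significance is supplied).
#' @export
classify_lineage_events <- function(focal_partition, sibling_prevalence,
                                    soft_min = 0.95, cloud_max = 0.15,
                                    conserved_min = 0.90,
                                    significance = NULL) {
  if (is.null(dim(sibling_prevalence)) || ncol(sibling_prevalence) == 0)
    pg_stop("sibling_prevalence must be a families x species matrix (no species given?)")
  cogs <- rownames(sibling_prevalence)
  if (is.null(cogs)) pg_stop("sibling_prevalence needs family row names")
  in_soft <- cogs %in% focal_partition$soft_core
  in_cloud <- cogs %in% focal_partition$cloud
  all_low <- apply(sibling_prevalence < cloud_max, 1, all)
  any_cons <- apply(sibling_prevalence >= conserved_min, 1, any)
  cls <- ifelse(in_soft & all_low, "GoF_candidate",
                ifelse(in_cloud & any_cons, "LoF_candidate", "none"))
  out <- data.frame(cog_id = cogs, lineage_class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(significance))
    out$event_class <- significance$class[match(out$cog_id,
                                                significance$cog_id)]
  out
}
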