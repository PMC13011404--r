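tree4 <- ape::read.tree(text = "((A,B),(C,D));")

test_that("Wagner parsimony handles the worked four-tip cases", {
  # all tips present: one origin gain at the root, cost 2
  ev <- wagner_events(tree4, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(ev$min_cost, 2)
  expect_equal(c(ev$gains, ev$losses), c(1, 0))
  expect_identical(ev$root_state, "present")

  # all tips absent: nothing happens
  ev0 <- wagner_events(tree4, c(A = 0, B = 0, C = 0, D = 0))
  expect_equal(ev0$min_cost, 0)
  expect_equal(c(ev0$gains, ev0$losses), c(0, 0))
  expect_identical(ev0$root_state, "absent")

  # clade-confined presence: one gain on the (A,B)-ancestor branch
  ev2 <- wagner_events(tree4, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(ev2$min_cost, 2)
  expect_equal(c(ev2$gains, ev2$losses), c(1, 0))
  expect_identical(ev2$root_state, "absent")
  expect_equal(nrow(ev2$per_branch), 1)
  ab_mrca <- ape::getMRCA(tree4, c("A", "B"))
  expect_equal(ev2$per_branch$child, ab_mrca)

  # {A, C}: cost 4 either way; the tie-break (fewer gains, then absence)
  # resolves to a present root with losses on the B and D branches
  ev3 <- wagner_events(tree4, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(ev3$min_cost, 4)
  expect_equal(c(ev3$gains, ev3$losses), c(1, 2))
  expect_identical(ev3$root_state, "present")
  expect_setequal(ev3$per_branch$child_label[ev3$per_branch$event == "loss"],
                  c("B", "D"))

  expect_error(wagner_events(tree4, c(A = 1, B = 1, C = 0)), "without a state")
})

test_that("Sankoff minima equal exhaustive enumeration on random trees", {
  set.seed(10)
  for (rep in 1:40) {
    ntip <- sample(4:10, 1)
    tr <- ape::rtree(ntip)
    x <- stats::setNames(rbinom(ntip, 1, 0.5), tr$tip.label)
    for (ro in c(TRUE, FALSE)) {
      ev <- wagner_events(tr, x, root_origin = ro)
      expect_equal(ev$min_cost, brute_wagner_cost(tr, x, root_origin = ro))
      # cost identity: gains and losses account for the whole cost
      expect_equal(ev$min_cost, 2 * ev$gains + ev$losses)
    }
  }
})

test_that("equal costs without origin reproduce Fitch parsimony counts", {
  skip_if_not_installed("phangorn")
  set.seed(11)
  for (rep in 1:20) {
    tr <- ape::rtree(8)
    x <- stats::setNames(rbinom(8, 1, 0.5), tr$tip.label)
    ev <- wagner_events(tr, x, gain_cost = 1, loss_cost = 1,
                        root_origin = FALSE)
    dat <- phangorn::phyDat(matrix(x, ncol = 1,
                                   dimnames = list(names(x), NULL)),
                            type = "USER", levels = c(0, 1))
    expect_equal(ev$min_cost, phangorn::fitch(tr, dat))
  }
})

test_that("matrix-level events memoise identical patterns and check tips", {
  set.seed(12)
  tr <- ape::rtree(10)
  m <- matrix(rbinom(10 * 20, 1, 0.4), 10, 20,
              dimnames = list(tr$tip.label, sprintf("c%02d", 1:20)))
  m[, 20] <- m[, 1]                         # duplicate pattern
  m <- validate_pa_matrix(m)
  pe <- pangenome_events(tr, m)
  s <- pe$summary
  dup <- s[s$cog_id %in% c("c01", "c20"), ]
  expect_equal(dup$gains[1], dup$gains[2])
  expect_equal(dup$min_cost[1], dup$min_cost[2])
  # all-ones matrix: every family one origin gain
  m1 <- matrix(1L, 10, 3, dimnames = list(tr$tip.label, c("x", "y", "z")))
  s1 <- pangenome_events(tr, m1)$summary
  expect_true(all(s1$gains == 1 & s1$losses == 0 & s1$min_cost == 2))

  bad <- m[1:9, , drop = FALSE]
  expect_error(pangenome_events(tr, bad), "differ")
})

test_that("low-rate histories are reconstructed on the true branches", {
  set.seed(13)
  tr <- ape::rcoal(32)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  gh <- simulate_gene_histories(tr, 300, gain_rate = 0.15, loss_rate = 0.15,
                                root_presence_prob = 0.3, seed = 14)
  total_ev <- colSums(gh$gain_events + gh$loss_events)
  single <- which(total_ev == 1 &
                    colSums(gh$matrix) > 0 & colSums(gh$matrix) < 32)
  m <- suppressWarnings(validate_pa_matrix(gh$matrix))
  pe <- pangenome_events(tr, m)
  hit <- vapply(single, function(j) {
    true_edge <- which(gh$gain_events[, j] + gh$loss_events[, j] == 1)
    id <- colnames(gh$matrix)[j]
    col <- match(id, pe$summary$cog_id)
    rec <- pe$gain_edge[, col] + pe$loss_edge[, col]
    sum(rec) >= 1 && rec[true_edge] >= 1
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("event significance classifies degenerate and clade-confined families", {
  set.seed(15)
  tr <- ape::rcoal(64)
  # pick an internal node whose clade holds about 8 tips
  sizes <- vapply((65):(64 + tr$Nnode), function(nd)
    length(ape::extract.clade(tr, nd)$tip.label), 0L)
  anc <- (65:(64 + tr$Nnode))[which.min(abs(sizes - 8))]
  desc <- ape::extract.clade(tr, anc)$tip.label
  m <- matrix(rbinom(64 * 6, 1, 0.4), 64, 6,
              dimnames = list(tr$tip.label, sprintf("r%d", 1:6)))
  m <- cbind(m, clade_cog = as.integer(tr$tip.label %in% desc),
             const_cog = 1L)
  m <- validate_pa_matrix(m)
  res <- event_significance(tr, m, n_label_perms = 200,
                            n_subsample_rounds = 0, seed = 16)
  expect_identical(res$class[res$cog_id == "const_cog"], "none")
  expect_equal(res$p_gain[res$cog_id == "const_cog"], 1)
  if (length(desc) >= 4) {
    z <- res$z_gain[res$cog_id == "clade_cog"]
    expect_lt(z, -1)      # far fewer gains than the shuffled null
    # conservation (fewer events than null) is not gain/loss signal
    expect_identical(res$class[res$cog_id == "clade_cog"], "none")
  }
})

test_that("lineage classification applies the prevalence thresholds", {
  G <- 100
  m <- matrix(0L, G, 20,
              dimnames = list(sprintf("g%03d", 1:G), sprintf("cog%02d", 1:20)))
  # 14 GoF-type: soft-core in the focal species
  for (j in 1:14) m[1:96, j] <- 1L
  # 4 LoF-type: cloud in the focal species
  for (j in 15:18) m[1:10, j] <- 1L
  # 2 uninteresting shell families
  m[1:50, 19:20] <- 1L
  part <- partition_pangenome(m)
  sib <- matrix(0.02, 20, 3,
                dimnames = list(colnames(m), c("spA", "spB", "spC")))
  sib[15:18, "spB"] <- 0.95                 # conserved in a sibling
  cls <- classify_lineage_events(part, sib)
  expect_identical(cls$lineage_class[1:14], rep("GoF_candidate", 14))
  expect_identical(cls$lineage_class[15:18], rep("LoF_candidate", 4))
  expect_identical(cls$lineage_class[19:20], rep("none", 2))

  # one sibling carrying the family above cloud_max disqualifies GoF
  sib2 <- sib; sib2[1, "spC"] <- 0.2
  cls2 <- classify_lineage_events(part, sib2)
  expect_identical(cls2$lineage_class[1], "none")
  # focal 10% + sibling 95%: LoF; focal 96% + all siblings low: GoF
  expect_identical(cls$lineage_class[15], "LoF_candidate")
})
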