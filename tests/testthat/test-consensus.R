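test_that("clade frequencies match a direct recount", {
  s1 <- toy_tree("((A,B),(C,D));"); s3 <- toy_tree("((A,C),(B,D));")
  sf <- split_frequencies(tree_sample(list(s1, s1, s3)))
  ab <- sf$p[sf$split == "1100"]
  expect_equal(ab, 2 / 3)
  # identical trees: every observed clade at p = 1
  same <- tree_sample(lapply(1:5, function(i) s1))
  expect_true(all(split_frequencies(same)$p == 1))
  # independent recount oracle (ape::prop.part) on random samples
  set.seed(11)
  trees <- lapply(1:30, function(i) {
    t <- rand_topology(6); t$tip.label <- paste0("t", 1:6); t
  })
  s <- tree_sample(trees)
  sf2 <- split_frequencies(s)
  pp <- ape::prop.part(structure(trees, class = "multiPhylo"))
  taxa <- sort(trees[[1]]$tip.label)
  for (i in seq_along(pp)) {
    tipset <- attr(pp, "labels")[pp[[i]]]
    if (length(tipset) < 2L || length(tipset) == 6L) next
    key <- fbdstrata:::mask_key(taxa %in% tipset)
    expect_equal(sf2$count[sf2$split == key], attr(pp, "number")[i])
  }
  expect_error(split_frequencies(structure(list(),
                                           class = c("tree_sample", "multiPhylo"))),
               "empty")
})

test_that("majority-rule consensus keeps exactly the majority clades", {
  s1 <- toy_tree("((A,B),(C,D));"); s3 <- toy_tree("((A,C),(B,D));")
  cons <- majority_rule_consensus(tree_sample(list(s1, s1, s3)))
  expect_setequal(cons$supports$split, c("1100", "0011"))
  expect_equal(cons$n_nodes, 2L)
  # identical trees: consensus is that topology with all supports 1
  same <- tree_sample(lapply(1:4, function(i) s1))
  c2 <- majority_rule_consensus(same)
  expect_true(all(c2$supports$p == 1))
  expect_equal(rf_dist(c2$tree, s1), 0L)
  # two incompatible trees: star, no non-trivial splits
  c3 <- majority_rule_consensus(tree_sample(list(s1, s3)))
  expect_equal(c3$n_nodes, 0L)
  expect_equal(c3$tree$Nnode, 1L)
  expect_error(majority_rule_consensus(same, threshold = 0.4), "0.5")
})

compatible <- function(a, b) {
  x <- fbdstrata:::split_bits(a); y <- fbdstrata:::split_bits(b)
  !any(x & y) || !any(x & !y) || !any(!x & y) || !any(!x & !y)
}

test_that("consensus clades are pairwise compatible on random samples", {
  set.seed(12)
  for (r in 1:5) {
    trees <- lapply(1:15, function(i) {
      t <- rand_topology(7); t$tip.label <- paste0("t", 1:7); t
    })
    cons <- majority_rule_consensus(tree_sample(trees))
    ks <- cons$supports$split
    if (length(ks) >= 2L)
      for (i in 1:(length(ks) - 1)) for (j in (i + 1):length(ks))
        expect_true(compatible(ks[i], ks[j]))
  }
})

test_that("the MCC tree equals the exhaustive clade-product argmax", {
  s1 <- toy_tree("((A,B),(C,D));"); s3 <- toy_tree("((A,C),(B,D));")
  one <- mcc_tree(tree_sample(list(s1)))
  expect_equal(one$index, 1L)
  expect_equal(one$sum_posteriors, s1$Nnode)   # every clade at p = 1
  dup <- mcc_tree(tree_sample(list(s1, s1, s3)))
  expect_equal(dup$index, 1L)
  # exhaustive oracle on a 30-tree fixture
  set.seed(13)
  trees <- lapply(1:30, function(i) {
    t <- rand_topology(6); t$tip.label <- paste0("t", 1:6); t
  })
  s <- tree_sample(trees)
  got <- mcc_tree(s)
  taxa <- sort(trees[[1]]$tip.label)
  counts <- table(unlist(lapply(trees, tree_clades, taxa = taxa)))
  score1 <- function(tr) sum(log(as.numeric(counts[tree_clades(tr, taxa)]) / 30))
  scores <- vapply(trees, score1, numeric(1))
  expect_equal(got$index, which.max(scores))
  expect_equal(got$score, max(scores))
  # the sum rule is also available and recorded
  expect_equal(mcc_tree(s, rule = "sum")$rule, "sum")
})

test_that("split information matches the double-factorial probabilities", {
  expect_equal(split_information(3, 6), -log2(9 / 105), tolerance = 1e-12)
  expect_equal(split_information(2, 6), log2(7), tolerance = 1e-12)
  expect_equal(as.numeric(split_information(1, 6)), 0)
  expect_true(attr(split_information(1, 6), "trivial"))
  expect_equal(split_information("111000"), -log2(9 / 105))
  # enumeration oracle at n = 6: tally containment over all 105 trees
  M <- enumerate_rooted_topologies(5)        # rooted 5-leaf = unrooted 6-leaf
  popcount <- function(m) sum(bitwAnd(m, 2^(0:8)) > 0)
  tab <- table(M)   # containment count per clade mask over all topologies
  for (k in names(tab)) {
    sz <- popcount(as.integer(k))
    if (sz < 2 || sz > 4) next
    frac <- as.integer(tab[[k]]) / nrow(M)
    expect_equal(as.numeric(split_information(sz, 6)), -log2(frac),
                 tolerance = 1e-9)
  }
})

test_that("consensus information composes split information", {
  s1 <- toy_tree("((A,B),(C,D));"); s3 <- toy_tree("((A,C),(B,D));")
  star <- majority_rule_consensus(tree_sample(list(s1, s3)))
  expect_equal(as.numeric(consensus_information(star)), 0)
  # fully resolved 6-taxon consensus of identical trees: one bit sum,
  # with the two root-child clades counted as a single bipartition
  tr <- toy_tree("(((A,B),C),((D,E),F));")
  cons <- majority_rule_consensus(tree_sample(lapply(1:3, function(i) tr)))
  want <- split_information("110000") + split_information("111000") +
    split_information("000110")
  expect_equal(as.numeric(consensus_information(cons, "plain")),
               as.numeric(want), tolerance = 1e-9)
  # support-weighted discounting can never exceed the plain content
  mixed <- majority_rule_consensus(tree_sample(list(tr, tr, rand_relabel(tr))))
  expect_lte(as.numeric(consensus_information(mixed, "support_weighted")),
             as.numeric(consensus_information(mixed, "plain")) + 1e-12)
  expect_error(consensus_information(cons, "bogus"))
})

test_that("a uniformly hopping taxon is detected as the first rogue", {
  s <- rogue_sample(n_trees = 40, seed = 21)
  rog <- detect_rogues(s)
  expect_gte(length(rog$rogues), 1L)
  expect_equal(rog$rogues[1], "X")
  expect_true(all(rog$gains > 0))
  expect_gte(rog$final_information, rog$initial_information)
  expect_equal(rog$mean_improvement, mean(rog$gains))
  # recomputation from scratch on the reduced sample agrees
  kept <- setdiff(attr(s, "leafset"), rog$rogues)
  reduced <- tree_sample(lapply(s, prune_to_leafset, keep = kept))
  expect_equal(rog$final_information,
               as.numeric(consensus_information(
                 majority_rule_consensus(reduced), rog$mode)),
               tolerance = 1e-9)
})

test_that("identical trees harbour no rogues", {
  tr <- toy_tree("(((A,B),C),((D,E),F));")
  rog <- detect_rogues(tree_sample(lapply(1:6, function(i) tr)))
  expect_length(rog$rogues, 0L)
  expect_equal(rog$mean_improvement, 0)
})

test_that("the consensus report bundles the summary statistics", {
  s <- rogue_sample(n_trees = 30, seed = 31)
  rep <- consensus_report(s)
  expect_equal(rep$n_nodes, rep$consensus$n_nodes)
  expect_equal(rep$n_rogues, length(rep$rogues$rogues))
  expect_lte(rep$sum_posteriors_mcc, rep$mcc$tree$Nnode)
  expect_gte(rep$information_content, 0)
})
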