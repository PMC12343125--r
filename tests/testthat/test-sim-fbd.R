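test_that("a rate-free process leaves one extant lineage spanning the origin", {
  p <- fbd_params(0, 0, 0, t_origin = 10, rho = 1, condition = "none")
  s <- simulate_fbd(p, seed = 1)
  expect_equal(nrow(s$tips), 1L)
  expect_equal(s$tips$role, "extant")
  expect_equal(s$tips$age, 0)
  expect_equal(nrow(s$fossils), 0L)
  expect_null(s$tree)                      # a single tip is not a phylo
  expect_equal(s$stem_length, 10)          # the whole origin-to-present edge
})

test_that("identical seeds reproduce the simulation bit for bit", {
  p <- fbd_params(0.2, 0.05, 0.3, 25, rho = 0.8, min_samples = 5)
  a <- simulate_fbd(p, seed = 7)
  b <- simulate_fbd(p, seed = 7)
  expect_identical(a, b)
  c <- simulate_fbd(p, seed = 8)
  expect_false(identical(a$species, c$species))
})

test_that("reconstructed trees satisfy the age and leafset invariants", {
  p <- fbd_params(0.25, 0.1, 0.3, 20, rho = 0.5, min_samples = 4)
  for (seed in 1:8) {
    s <- simulate_fbd(p, seed = seed)
    if (is.null(s$tree)) next
    a <- node_ages(s$tree)
    E <- s$tree$edge
    expect_true(all(a[E[, 1L]] - a[E[, 2L]] >= -1e-9))
    expect_true(all(a >= -1e-9))
    expect_setequal(s$tree$tip.label, s$tips$taxon)
    # sampled ancestors sit on zero-length pendant edges
    sa <- s$tips$taxon[s$tips$role == "sampled_ancestor"]
    for (t in sa) {
      i <- match(t, s$tree$tip.label)
      expect_equal(s$tree$edge.length[E[, 2L] == i], 0)
    }
    # tip ages equal the youngest retained sample of the species
    expect_equal(unname(tip_ages(s$tree)[s$tips$taxon]), s$tips$age,
                 tolerance = 1e-9)
  }
})

test_that("pure-birth tip counts track the Yule expectation", {
  p <- fbd_params(0.3, 0, 0, 10, rho = 1, condition = "none",
                  max_lineages = 20000)
  tips <- vapply(1:400, function(s)
    nrow(simulate_fbd(p, seed = s)$tips), numeric(1))
  expected <- exp(0.3 * 10)
  se <- sd(tips) / sqrt(length(tips))
  expect_lt(abs(mean(tips) - expected), 3 * se)
})

test_that("genus assignment follows the stem-crossing rule", {
  h <- balanced_history()
  expect_equal(unname(table(assign_genera(h, 8))[c("G2", "G3")]),
               c(2L, 2L), ignore_attr = TRUE)
  g <- assign_genera(h, 8)
  expect_equal(unname(g[c("t4", "t5")]), c("G2", "G2"))
  expect_equal(unname(g[c("t6", "t7")]), c("G3", "G3"))
  # tau just below the origin: one genus holds everything
  expect_equal(length(unique(assign_genera(h, 11.5))), 1L)
  # tau just above the present: every terminal edge is its own genus
  expect_equal(length(unique(assign_genera(h, 0.5))), 4L)
  expect_error(assign_genera(h, 13), "tau_genus")
  expect_error(assign_genera(h, 0), "tau_genus")
})

test_that("assigned genera are monophyletic on the reconstructed tree", {
  p <- fbd_params(0.25, 0.05, 0.3, 30, rho = 0.5, min_samples = 8)
  s <- simulate_fbd(p, seed = 11)
  g <- assign_genera(s, tau_genus = 15)
  expect_setequal(names(g), s$tips$taxon)   # partition of the sampled taxa
  for (gen in unique(g)) {
    members <- names(g)[g == gen]
    if (length(members) < 2L || length(members) == nrow(s$tips)) next
    mrca <- ape::getMRCA(s$tree, members)
    desc <- ape::extract.clade(s$tree, mrca)$tip.label
    expect_true(all(g[desc] == gen))        # MRCA subtree stays in-genus
  }
})

test_that("character simulation has the right marginal behaviour", {
  tr <- toy_tree("(A:0.5,B:0.7);")
  m0 <- simulate_characters(tr, 30, seed = 2, rates = rep(0, 30))
  expect_true(all(apply(m0, 2L, function(col) length(unique(col)) == 1L)))
  m1 <- simulate_characters(tr, 10, seed = 2, missing_frac = 1)
  expect_true(all(is.na(m1)))
  # closed-form two-state mismatch probability over the 1.2-myr path
  m <- simulate_characters(tr, 10000, n_states = 2, gamma_shape = Inf, seed = 5)
  p_hat <- mean(m["A", ] != m["B", ])
  p_exp <- (1 - exp(-2 * 1.2)) / 2
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
  expect_identical(simulate_characters(tr, 50, seed = 9),
                   simulate_characters(tr, 50, seed = 9))
})

test_that("morphology-set selection is abundance-biased as (count)^beta", {
  occ <- data.frame(taxon = rep(c("a", "b"), times = c(4, 1)))
  picks <- vapply(1:4000, function(s)
    select_morph_taxa(occ, 1, beta = 1, seed = s), character(1))
  p_hat <- mean(picks == "a")
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / 4000))
  # beta = 0: uniform regardless of counts
  picks0 <- vapply(1:2000, function(s)
    select_morph_taxa(occ, 1, beta = 0, seed = s), character(1))
  expect_gt(chisq.test(table(picks0), p = c(0.5, 0.5))$p.value, 0.01)
  # dominant count wins in the large-beta limit
  occ2 <- data.frame(taxon = rep(c("a", "b", "c"), times = c(10, 2, 1)))
  picks2 <- vapply(1:50, function(s)
    select_morph_taxa(occ2, 1, beta = 50, seed = s), character(1))
  expect_true(all(picks2 == "a"))
  expect_error(select_morph_taxa(occ, 5, seed = 1), "exceeds")
})

test_that("stage binning contains the true age and ties go to the older stage", {
  sc <- timescale(seq(60, 0, by = -5))
  occ <- data.frame(occurrence_id = 1:3, taxon = "t1", genus = NA,
                    rank = "species", max_ma = 0, min_ma = 0,
                    true_ma = c(12.3, 10, 60))
  b <- bin_occurrence_ages(occ, sc, p_coarse = 0, seed = 1)
  expect_equal(b$max_ma, c(15, 15, 60))
  expect_equal(b$min_ma, c(10, 10, 55))
  # full-scale widening
  b2 <- bin_occurrence_ages(occ, sc, p_coarse = 1, coarse_stages = Inf, seed = 1)
  expect_true(all(b2$max_ma == 60 & b2$min_ma == 0))
  # partial widening still contains the truth
  occ$true_ma <- runif(3, 0, 60)
  b3 <- bin_occurrence_ages(occ, sc, p_coarse = 1, coarse_stages = 3, seed = 4)
  expect_true(all(b3$true_ma <= b3$max_ma & b3$true_ma >= b3$min_ma))
  occ$true_ma[2] <- 99
  expect_error(bin_occurrence_ages(occ, sc), "outside the timescale")
})

test_that("pseudo-posteriors degenerate to the truth without noise", {
  s <- simulate_fbd(fbd_params(0.25, 0.05, 0.3, 25, rho = 0.5,
                               min_samples = 6), seed = 3)
  ps <- generate_pseudo_posterior(s$tree, 10, nni_rate = 0,
                                  age_jitter_sd = 0, seed = 1)
  for (tr in ps) {
    expect_equal(rf_dist(tr, s$tree), 0L)
    expect_equal(node_ages(tr), node_ages(s$tree), tolerance = 1e-12)
  }
})

test_that("topological noise grows with the NNI rate", {
  s <- simulate_fbd(fbd_params(0.25, 0.05, 0.3, 25, rho = 0.5,
                               min_samples = 10), seed = 5)
  mean_rf <- vapply(c(0.5, 2, 8), function(rate) {
    ps <- generate_pseudo_posterior(s$tree, 100, nni_rate = rate,
                                    age_jitter_sd = 0, seed = 17)
    mean(vapply(ps, rf_dist, numeric(1), t2 = s$tree))
  }, numeric(1))
  expect_true(all(diff(mean_rf) > 0))
})

test_that("congruence weighting lowers the sample's implied gaps", {
  s <- simulate_fbd(fbd_params(0.25, 0.05, 0.3, 25, rho = 0.5,
                               min_samples = 8), seed = 6)
  ages <- data.frame(taxon = s$tips$taxon, max_ma = s$tips$age,
                     min_ma = s$tips$age)
  fads <- setNames(ages$max_ma, ages$taxon)
  wins <- 0L
  for (r in 1:5) {
    p0 <- generate_pseudo_posterior(s$tree, 30, nni_rate = 3,
                                    age_jitter_sd = 0.05,
                                    congruence_weight = 0, seed = 100 + r)
    p5 <- generate_pseudo_posterior(s$tree, 30, nni_rate = 3,
                                    age_jitter_sd = 0.05,
                                    congruence_weight = 5, ages = ages,
                                    seed = 200 + r)
    m0 <- mean(vapply(p0, mig, numeric(1), fads = fads))
    m5 <- mean(vapply(p5, mig, numeric(1), fads = fads))
    wins <- wins + (m5 < m0)
  }
  expect_gte(wins, 4L)
})
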