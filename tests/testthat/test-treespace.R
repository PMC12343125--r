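# brute-force clustering-information distance by scanning all split matchings
perm_cid <- function(t1, t2) {
  taxa <- sort(t1$tip.label); n <- length(taxa)
  b1 <- lapply(fbdstrata:::tree_splits(t1, taxa), fbdstrata:::split_bits)
  b2 <- lapply(fbdstrata:::tree_splits(t2, taxa), fbdstrata:::split_bits)
  h <- function(b) fbdstrata:::split_entropy(sum(b), n)
  H <- sum(vapply(b1, h, numeric(1))) + sum(vapply(b2, h, numeric(1)))
  m <- max(length(b1), length(b2))
  W <- matrix(0, m, m)
  for (i in seq_along(b1)) for (j in seq_along(b2))
    W[i, j] <- fbdstrata:::split_mutual_info(b1[[i]], b2[[j]])
  perms <- function(v) if (length(v) <= 1L) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- max(vapply(perms(seq_len(m)), function(p)
    sum(W[cbind(seq_len(m), p)]), numeric(1)))
  max(0, H - 2 * best)
}

test_that("RF distance counts the split symmetric difference", {
  t1 <- rand_topology(6)
  expect_equal(rf_dist(t1, t1), 0L)
  a <- toy_tree("((A,B),(C,D));"); b <- toy_tree("((A,C),(B,D));")
  expect_equal(rf_dist(a, b), 2L)
  set.seed(2)
  for (r in 1:30) {
    x <- rand_topology(8); y <- rand_topology(8)
    y$tip.label <- x$tip.label
    expect_equal(rf_dist(x, y), as.integer(phangorn::RF.dist(x, y)))
    expect_lte(rf_dist(x, y), 2L * (8L - 3L))
  }
  y5 <- rand_topology(5)
  expect_error(rf_dist(t1, y5), "leafset")
})

test_that("clustering-information distance matches the exhaustive matching", {
  set.seed(3)
  for (r in 1:20) {
    x <- rand_topology(6); y <- rand_topology(6)
    y$tip.label <- x$tip.label
    expect_equal(clustering_info_dist(x, y), perm_cid(x, y), tolerance = 1e-9)
    expect_equal(clustering_info_dist(x, y), clustering_info_dist(y, x))
  }
  x <- rand_topology(7)
  expect_identical(clustering_info_dist(x, x), 0)
})

test_that("both tree distances satisfy the metric axioms", {
  set.seed(4)
  for (r in 1:25) {
    trs <- lapply(1:3, function(i) {
      t <- rand_topology(7); t$tip.label <- paste0("t", 1:7); t
    })
    for (f in list(rf_dist, clustering_info_dist)) {
      dab <- f(trs[[1]], trs[[2]]); dac <- f(trs[[1]], trs[[3]])
      dbc <- f(trs[[2]], trs[[3]])
      expect_gte(dab, 0)
      expect_equal(dab, f(trs[[2]], trs[[1]]))
      expect_lte(dac, dab + dbc + 1e-9)       # triangle inequality
    }
  }
})

test_that("distance matrices are exact, symmetric and zero-diagonal", {
  t0 <- rand_topology(6)
  same <- tree_sample(lapply(1:4, function(i) t0))
  expect_true(all(tree_distance_matrix(same, "rf") == 0))
  expect_true(all(tree_distance_matrix(same, "cid") == 0))
  set.seed(5)
  trees <- lapply(1:8, function(i) {
    t <- rand_topology(6); t$tip.label <- paste0("t", 1:6); t
  })
  s <- tree_sample(trees)
  for (metric in c("rf", "cid")) {
    D <- tree_distance_matrix(s, metric)
    expect_true(isSymmetric(D))
    expect_true(all(diag(D) == 0))
    f <- if (metric == "rf") rf_dist else clustering_info_dist
    expect_equal(D[2, 5], f(trees[[2]], trees[[5]]), tolerance = 1e-9)
    expect_equal(D[1, 8], f(trees[[1]], trees[[8]]), tolerance = 1e-9)
  }
  expect_equal(tree_distance_matrix(tree_sample(list(t0))), matrix(0, 1, 1))
})

test_that("PCoA recovers planted configurations", {
  # three collinear points
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  e <- suppressWarnings(pcoa_embed(D, k = 2))
  x <- e$points[, 1]
  expect_equal(sort(x - mean(x)), c(-1, 0, 1), tolerance = 1e-9)
  expect_true(all(diff(e$eig) <= 1e-9))        # non-increasing spectrum
  # planted 2-D cloud: recovered up to rigid transform
  set.seed(6)
  X <- matrix(rnorm(24), 12, 2)
  e2 <- pcoa_embed(as.matrix(dist(X)), k = 2)
  pro <- vegan::procrustes(X, e2$points, symmetric = FALSE)
  expect_lt(sum(pro$residuals^2), 1e-8)
  # reconstructed distances match the Euclidean input
  expect_equal(as.matrix(dist(e2$points)), as.matrix(dist(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  z <- pcoa_embed(matrix(0, 4, 4), k = 2)
  expect_true(all(z$points == 0))
  expect_error(pcoa_embed(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("the landscape anchors at data points and interpolates between", {
  emb <- structure(list(points = cbind(c(-2, -2, 2, 2), c(-1, 1, -1, 1)),
                        eig = c(1, 1), k = 2, group = NULL,
                        values = c(10, 10, 30, 30)),
                   class = "treespace_embedding")
  ls <- treespace_landscape(emb, grid_n = 41)
  # constant surface when all values equal
  flat <- treespace_landscape(emb, values = rep(5, 4), grid_n = 21)
  expect_true(all(abs(flat$z - 5) < 1e-9, na.rm = TRUE))
  # value at a data point equals that point's value
  gx <- which.min(abs(ls$x - -2)); gy <- which.min(abs(ls$y - -1))
  expect_equal(ls$z[gx, gy], 10, tolerance = 1e-6)
  # monotone gradient along the axis joining two clusters
  mid <- which.min(abs(ls$y - 0))
  prof <- ls$z[, mid]
  prof <- prof[!is.na(prof)]
  expect_true(all(diff(prof) > -1e-9))
  # permuting the input leaves the surface unchanged
  perm <- c(3, 1, 4, 2)
  emb2 <- emb; emb2$points <- emb$points[perm, ]; emb2$values <- emb$values[perm]
  ls2 <- treespace_landscape(emb2, grid_n = 41)
  expect_equal(ls2$z, ls$z)
})

test_that("densities integrate to one and peak where points cluster", {
  set.seed(7)
  pts <- rbind(matrix(rnorm(100, 0, 0.5), 50, 2),
               matrix(rnorm(100, 4, 0.5), 50, 2))
  emb <- structure(list(points = pts, eig = c(1, 1), k = 2,
                        group = rep(c("a", "b"), each = 50), values = NULL),
                   class = "treespace_embedding")
  den <- treespace_density(emb, grid_n = 81)
  for (g in c("a", "b")) {
    z <- den[[g]]
    cell <- diff(z$x[1:2]) * diff(z$y[1:2])
    expect_lt(abs(sum(z$z) * cell - 1), 0.01)
  }
  # unimodal cluster peaks at its centroid
  peak <- which(den$a$z == max(den$a$z), arr.ind = TRUE)
  expect_lt(abs(den$a$x[peak[1]] - 0), 0.5)
  expect_lt(abs(den$a$y[peak[2]] - 0), 0.5)
  emb$points[1:50, 1] <- 0                     # degenerate axis
  expect_warning(treespace_density(emb, grid_n = 21), "delta")
})

test_that("spread statistics use population variance and centroid distance", {
  one <- structure(list(points = matrix(c(1, 2), 1, 2), eig = 0, k = 2,
                        group = "g", values = NULL),
                   class = "treespace_embedding")
  s1 <- spread_stats(one)
  expect_equal(unlist(s1[, c("sum_variance", "sum_range",
                             "mean_centroid_dist")]),
               c(0, 0, 0), ignore_attr = TRUE)
  two <- structure(list(points = rbind(c(0, 0), c(2, 0)), eig = c(1, 0),
                        k = 2, group = c("g", "g"), values = NULL),
                   class = "treespace_embedding")
  s2 <- spread_stats(two)
  expect_equal(s2$sum_variance, 1)             # population (1/n) variance
  expect_equal(s2$sum_range, 2)
  expect_equal(s2$mean_centroid_dist, 1)
  # duplicating the cloud leaves every statistic unchanged
  four <- structure(list(points = rbind(c(0, 0), c(2, 0), c(0, 0), c(2, 0)),
                         eig = c(1, 0), k = 2, group = rep("g", 4),
                         values = NULL), class = "treespace_embedding")
  expect_equal(spread_stats(four)[, -2], s2[, -2])
})

test_that("distance-matrix spread equals the full-space embedding version", {
  # two-point worked case straight from distances
  D2 <- matrix(c(0, 2, 2, 0), 2, 2)
  sD <- spread_stats(D2, group = c("g", "g"))
  expect_equal(sD$sum_variance, 1)
  expect_equal(sD$mean_centroid_dist, 1)
  # Euclidean cloud: distance route agrees with per-axis statistics on the
  # full-dimensional coordinates
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  grp <- rep(c("a", "b"), each = 10)
  D <- as.matrix(dist(X))
  sD2 <- spread_stats(D, group = grp)
  popvar <- function(x) mean((x - mean(x))^2)
  for (g in c("a", "b")) {
    P <- X[grp == g, ]
    expect_equal(sD2$sum_variance[sD2$group == g],
                 sum(apply(P, 2, popvar)), tolerance = 1e-8)
    ctr <- colMeans(P)
    expect_equal(sD2$mean_centroid_dist[sD2$group == g],
                 mean(sqrt(rowSums(sweep(P, 2, ctr)^2))), tolerance = 1e-8)
  }
})
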