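## Treespace: pairwise tree distances, principal-coordinates embedding, the
## stratigraphic congruence "landscape" and per-group density map, and
## distribution-spread statistics for posterior tree samples.

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the trees' non-trivial bipartition
#' sets (trees compared as unrooted).
#'
#' @param t1,t2 `phylo` objects on the same leafset.
#' @return integer distance.
#' @export
rf_dist <- function(t1, t2) {
  taxa <- sort(t1$tip.label)
  if (!identical(taxa, sort(t2$tip.label))) stop("leafset mismatch")
  s1 <- tree_splits(t1, taxa); s2 <- tree_splits(t2, taxa)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

## ---- clustering-information distance ------------------------------------

split_entropy <- function(a, n) {
  p <- c(a, n - a) / n
  -sum(p * log2(p))
}

# vectorized mutual information (bits) between all rows of two split
# matrices (logical, splits x taxa)
mi_matrix <- function(B1, B2) {
  n <- ncol(B1)
  a1 <- rowSums(B1); a2 <- rowSums(B2)
  N11 <- B1 %*% t(B2)
  N10 <- a1 - N11
  N01 <- matrix(a2, nrow(B1), nrow(B2), byrow = TRUE) - N11
  N00 <- n - N11 - N10 - N01
  term <- function(Nij, ai, bj) {
    A <- matrix(ai, nrow(Nij), ncol(Nij))
    B <- matrix(bj, nrow(Nij), ncol(Nij), byrow = TRUE)
    out <- Nij / n * log2((Nij * n) / (A * B))
    out[Nij == 0] <- 0
    out
  }
  term(N11, a1, a2) + term(N10, a1, n - a2) +
    term(N01, n - a1, a2) + term(N00, n - a1, n - a2)
}

# mutual information (bits) between two bipartitions of the same n leaves
split_mutual_info <- function(b1, b2) {
  n <- length(b1)
  mi <- 0
  for (s1 in c(TRUE, FALSE)) for (s2 in c(TRUE, FALSE)) {
    nij <- sum((b1 == s1) & (b2 == s2))
    if (nij == 0L) next
    pi <- sum(b1 == s1) / n; pj <- sum(b2 == s2) / n
    mi <- mi + (nij / n) * log2((nij / n) / (pi * pj))
  }
  mi
}

# Exact min-cost assignment (Hungarian / shortest augmenting path with
# potentials). Square cost matrix; returns the column assigned to each row.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)   # v[1] is the dummy column 0
  p <- integer(n + 1L)                          # p[j+1]: row matched to col j
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n); way <- integer(n); used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) if (!used[j + 1L]) {
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  assignment
}

split_bits <- function(key) as.logical(as.integer(strsplit(key, "")[[1L]]))

#' Clustering-information distance between two trees (bits)
#'
#' Generalized Robinson-Foulds distance in which splits are matched by
#' optimal assignment maximizing the mutual clustering information they
#' share: `d = H(T1) + H(T2) - 2 * max-matching mutual information`, where
#' `H(T)` sums the entropies of the tree's non-trivial splits. Symmetric,
#' non-negative, and 0 exactly when the split sets are identical.
#'
#' @inheritParams rf_dist
#' @return distance in bits.
#' @export
clustering_info_dist <- function(t1, t2) {
  taxa <- sort(t1$tip.label)
  if (!identical(taxa, sort(t2$tip.label))) stop("leafset mismatch")
  n <- length(taxa)
  k1 <- tree_splits(t1, taxa); k2 <- tree_splits(t2, taxa)
  if (setequal(k1, k2)) return(0)
  b1 <- lapply(k1, split_bits); b2 <- lapply(k2, split_bits)
  h1 <- sum(vapply(b1, function(b) split_entropy(sum(b), n), numeric(1)))
  h2 <- sum(vapply(b2, function(b) split_entropy(sum(b), n), numeric(1)))
  if (!length(b1) || !length(b2)) return(h1 + h2)
  m <- max(length(b1), length(b2))
  W <- matrix(0, m, m)    # padded with zero-information dummy splits
  for (i in seq_along(b1)) for (j in seq_along(b2))
    W[i, j] <- split_mutual_info(b1[[i]], b2[[j]])
  asg <- hungarian_assign(max(W) - W)
  score <- sum(W[cbind(seq_len(m), asg)])
  max(0, h1 + h2 - 2 * score)
}

#' Pairwise distance matrix over a tree sample
#'
#' @param sample a [tree_sample()].
#' @param metric `"cid"` (clustering information, the default) or `"rf"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
tree_distance_matrix <- function(sample, metric = c("cid", "rf")) {
  metric <- match.arg(metric)
  taxa <- attr(sample, "leafset")
  if (is.null(taxa)) taxa <- sort(sample[[1L]]$tip.label)
  n <- length(sample)
  keysets <- lapply(sample, tree_splits, taxa = taxa)
  nt <- length(taxa)
  D <- matrix(0, n, n)
  if (metric == "rf") {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- length(setdiff(keysets[[i]], keysets[[j]])) +
           length(setdiff(keysets[[j]], keysets[[i]]))
      D[i, j] <- D[j, i] <- d
    }
    return(D)
  }
  # mutual information is precomputed once over the sample's unique splits
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  B <- if (length(all_keys))
    t(vapply(all_keys, split_bits, logical(nt))) else matrix(FALSE, 0L, nt)
  MI <- if (nrow(B)) mi_matrix(B, B) else matrix(0, 0L, 0L)
  idx <- lapply(keysets, match, table = all_keys)
  ent1 <- if (nrow(B))
    vapply(seq_len(nrow(B)), function(i) split_entropy(sum(B[i, ]), nt),
           numeric(1)) else numeric(0)
  ent <- vapply(idx, function(ii) sum(ent1[ii]), numeric(1))
  # distances depend on trees only through their split sets: dedupe
  sig <- vapply(keysets, function(ks) paste(sort(ks), collapse = "|"),
                character(1))
  uniq <- !duplicated(sig)
  umap <- match(sig, sig[uniq])
  uidx <- which(uniq)
  nu <- length(uidx)
  UD <- matrix(0, nu, nu)
  for (a in seq_len(nu - 1L)) for (b in (a + 1L):nu) {
    i <- uidx[a]; j <- uidx[b]
    i1 <- idx[[i]]; i2 <- idx[[j]]
    if (!length(i1) || !length(i2)) { d <- ent[i] + ent[j] }
    else {
      m <- max(length(i1), length(i2))
      W <- matrix(0, m, m)
      W[seq_along(i1), seq_along(i2)] <- MI[i1, i2, drop = FALSE]
      asg <- hungarian_assign(max(W) - W)
      d <- max(0, ent[i] + ent[j] - 2 * sum(W[cbind(seq_len(m), asg)]))
    }
    UD[a, b] <- UD[b, a] <- d
  }
  D <- UD[umap, umap, drop = FALSE]
  diag(D) <- 0
  dimnames(D) <- NULL
  D
}

## ---- embedding ----------------------------------------------------------

#' Principal-coordinates embedding of a distance matrix
#'
#' Classical PCoA via double-centring and eigendecomposition
#' (`stats::cmdscale`). Axes with non-positive eigenvalues are dropped with
#' a warning; the full eigenvalue spectrum is always reported so that
#' variation beyond the retained axes is visible rather than guessed at.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k number of axes to retain (capped at the positive spectrum).
#' @param group optional per-tree group labels.
#' @param values optional per-tree values (e.g. MIG) carried alongside.
#' @return object of class `treespace_embedding`: list with `points`
#'   (n x k'), `eig` (full spectrum, non-increasing), `k`, `group`,
#'   `values`, `metric`.
#' @export
pcoa_embed <- function(D, k = 2L, group = NULL, values = NULL) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(D)
  if (n == 1L) {
    return(structure(list(points = matrix(0, 1L, 1L), eig = 0, k = 1L,
                          group = group, values = values, metric = NA),
                     class = "treespace_embedding"))
  }
  if (all(D == 0)) {
    return(structure(list(points = matrix(0, n, k), eig = rep(0, n), k = k,
                          group = group, values = values, metric = NA),
                     class = "treespace_embedding"))
  }
  mds <- suppressWarnings(stats::cmdscale(D, k = min(k, n - 1L), eig = TRUE))
  eig <- sort(mds$eig, decreasing = TRUE)
  pos <- sum(mds$eig > 1e-9)
  keep <- min(k, pos)
  if (keep < k)
    warning("dropping ", k - keep, " axes with non-positive eigenvalues")
  pts <- mds$points[, seq_len(keep), drop = FALSE]
  structure(list(points = pts, eig = eig, k = keep, group = group,
                 values = values, metric = NA),
            class = "treespace_embedding")
}

#' @export
print.treespace_embedding <- function(x, ...) {
  cat("Treespace embedding: ", nrow(x$points), " trees, ", ncol(x$points),
      " retained axes\n", sep = "")
  pe <- x$eig[x$eig > 0]
  if (length(pe))
    cat("Variance on first two axes: ",
        round(100 * sum(pe[seq_len(min(2, length(pe)))]) / sum(pe), 1),
        "%\n", sep = "")
  invisible(x)
}

embedding_xy <- function(embedding) {
  pts <- embedding$points
  if (ncol(pts) < 2L) pts <- cbind(pts, 0)   # pad degenerate embeddings
  pts[, 1:2, drop = FALSE]
}

#' Interpolated value surface over treespace (the congruence "landscape")
#'
#' Inverse-distance-weighted interpolation of a per-tree value (e.g. MIG)
#' over a grid on the first two embedding axes, masked to the convex hull of
#' the points. The surface equals the tree's value at each tree location.
#'
#' @param embedding a [pcoa_embed()] result.
#' @param values per-tree values; defaults to `embedding$values`.
#' @param grid_n grid resolution per axis.
#' @param power IDW power.
#' @return list `x`, `y` (grid axes), `z` (matrix, `NA` outside the hull),
#'   class `treespace_landscape`.
#' @export
treespace_landscape <- function(embedding, values = embedding$values,
                                grid_n = 101L, power = 2) {
  pts <- embedding_xy(embedding)
  stopifnot(length(values) == nrow(pts))
  rx <- range(pts[, 1L]); ry <- range(pts[, 2L])
  pad <- function(r) if (diff(r) == 0) r + c(-1, 1) else r
  rx <- pad(rx); ry <- pad(ry)
  gx <- seq(rx[1L], rx[2L], length.out = grid_n)
  gy <- seq(ry[1L], ry[2L], length.out = grid_n)
  hull <- pts[chull(pts), , drop = FALSE]
  # inflate the hull a whisker so its own vertices classify as inside
  ctr <- colMeans(hull)
  hull <- sweep(sweep(hull, 2L, ctr) * (1 + 1e-9), 2L, ctr, `+`)
  gpts <- cbind(rep(gx, times = grid_n), rep(gy, each = grid_n))
  inside <- if (nrow(hull) >= 3L) mgcv::in.out(rbind(hull, hull[1L, ]), gpts)
            else rep(TRUE, nrow(gpts))
  z <- rep(NA_real_, nrow(gpts))
  for (g in which(inside)) {
    d2 <- (pts[, 1L] - gpts[g, 1L])^2 + (pts[, 2L] - gpts[g, 2L])^2
    hit <- which(d2 < 1e-20)
    if (length(hit)) { z[g] <- values[hit[1L]]; next }
    w <- 1 / d2^(power / 2)
    z[g] <- sum(w * values) / sum(w)
  }
  structure(list(x = gx, y = gy, z = matrix(z, grid_n, grid_n),
                 points = pts, values = values),
            class = "treespace_landscape")
}

#' Per-group kernel density over treespace
#'
#' 2-D normal-kernel density (`MASS::kde2d`, normal-reference bandwidth) on
#' the first two embedding axes, computed per group on a common grid padded
#' well beyond the data so each surface integrates to 1 over the grid.
#'
#' @param embedding a [pcoa_embed()] result.
#' @param group per-tree group labels; defaults to `embedding$group`.
#' @param grid_n grid resolution per axis.
#' @param bw optional bandwidth (length 2), otherwise normal-reference.
#' @return named list of `MASS::kde2d` surfaces, class `treespace_density`.
#' @export
treespace_density <- function(embedding, group = embedding$group,
                              grid_n = 101L, bw = NULL) {
  pts <- embedding_xy(embedding)
  if (is.null(group)) group <- rep("all", nrow(pts))
  stopifnot(length(group) == nrow(pts))
  nrd_safe <- function(x) {
    h <- MASS::bandwidth.nrd(x)
    if (!is.finite(h) || h <= 0) h <- max(1e-3, diff(range(x)) / 4, 1e-3)
    h
  }
  if (is.null(bw)) bw <- c(nrd_safe(pts[, 1L]), nrd_safe(pts[, 2L]))
  lims <- c(range(pts[, 1L]) + c(-4, 4) * bw[1L],
            range(pts[, 2L]) + c(-4, 4) * bw[2L])
  out <- lapply(split(seq_len(nrow(pts)), group), function(idx) {
    if (length(idx) < 2L) stop("need at least 2 points per group")
    P <- pts[idx, , drop = FALSE]
    if (any(apply(P, 2L, function(x) diff(range(x)) == 0)))
      warning("all points of a group identical on an axis; ",
              "density is delta-like")
    MASS::kde2d(P[, 1L], P[, 2L], h = bw, n = grid_n, lims = lims)
  })
  structure(out, class = "treespace_density", bw = bw)
}

#' Spread statistics of point clouds in treespace
#'
#' Per group: sum of (population) variances, sum of coordinate ranges, and
#' mean Euclidean distance to the group centroid. Used to compare how
#' tightly two posterior distributions cluster.
#'
#' Given an embedding, the statistics are computed across its retained axes.
#' Given the full distance matrix, they are computed in the full space --
#' `sum_variance` from the identity `sum(d^2)/(2 n^2)` over within-group
#' pairs and centroid distances by Gower centring -- which avoids the
#' truncation bias of a low-dimensional projection (axes beyond those
#' retained can hold real spread); `sum_range` then comes from the full
#' positive-eigenvalue embedding.
#'
#' @param x a [pcoa_embed()] result, or a symmetric distance matrix.
#' @param group per-point group labels (defaults to `x$group` for an
#'   embedding).
#' @return data frame (`group`, `n`, `sum_variance`, `sum_range`,
#'   `mean_centroid_dist`).
#' @export
spread_stats <- function(x, group = NULL) {
  if (is.matrix(x) && is.numeric(x)) return(spread_stats_dist(x, group))
  pts <- x$points
  if (is.null(group)) group <- x$group
  if (is.null(group)) group <- rep("all", nrow(pts))
  if (any(table(group) < 1L)) stop("empty group")
  rows <- lapply(split(seq_len(nrow(pts)), group), function(idx) {
    P <- pts[idx, , drop = FALSE]
    ctr <- colMeans(P)
    popvar <- function(x) mean((x - mean(x))^2)
    data.frame(n = length(idx),
               sum_variance = sum(apply(P, 2L, popvar)),
               sum_range = sum(apply(P, 2L, function(x) diff(range(x)))),
               mean_centroid_dist =
                 mean(sqrt(rowSums(sweep(P, 2L, ctr)^2))))
  })
  out <- do.call(rbind, rows)
  data.frame(group = names(rows), out, row.names = NULL)
}

spread_stats_dist <- function(D, group) {
  if (is.null(group)) group <- rep("all", nrow(D))
  stopifnot(length(group) == nrow(D))
  full <- if (nrow(D) > 1L && any(D > 0))
    suppressWarnings(pcoa_embed(D, k = nrow(D) - 1L)) else NULL
  rows <- lapply(split(seq_len(nrow(D)), group), function(idx) {
    Dg <- D[idx, idx, drop = FALSE]
    ng <- length(idx)
    sv <- sum(Dg^2) / (2 * ng^2)
    # squared distance to the group centroid via Gower centring
    c2 <- pmax(0, colSums(Dg^2) / ng - sum(Dg^2) / (2 * ng^2))
    sr <- if (is.null(full)) 0 else
      sum(apply(full$points[idx, , drop = FALSE], 2L,
                function(x) diff(range(x))))
    data.frame(n = ng, sum_variance = sv, sum_range = sr,
               mean_centroid_dist = mean(sqrt(c2)))
  })
  out <- do.call(rbind, rows)
  data.frame(group = names(rows), out, row.names = NULL)
}
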