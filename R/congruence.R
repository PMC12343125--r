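## Stratigraphic congruence of dated topologies against first appearance
## data (FADs). Under minimal node dating -- every internal node as young as
## its oldest descendant FAD allows -- each branch implies a ghost range:
## time during which the lineage must have existed but left no sampled
## fossils. MIG is the summed ghost range; GER rescales MIG between its
## best (g_min) and worst (g_max) values over all topologies; SCI is the
## proportion of nodes whose clade does not first appear before its sister.

as_fad_vector <- function(ages, convention = c("max", "midpoint")) {
  convention <- match.arg(convention)
  if (is.numeric(ages)) {
    if (is.null(names(ages))) stop("FAD vector must be named by taxon")
    return(ages)
  }
  stopifnot(is.data.frame(ages), all(c("taxon", "max_ma") %in% names(ages)))
  v <- switch(convention,
              max = ages$max_ma,
              midpoint = (ages$max_ma + ages$min_ma) / 2)
  setNames(v, ages$taxon)
}

check_fads <- function(phy, fads) {
  miss <- setdiff(phy$tip.label, names(fads))
  if (length(miss))
    stop("missing FAD for taxon: ", paste(miss, collapse = ", "))
  fads[phy$tip.label]
}

#' Minimal node ages consistent with first appearance data
#'
#' Each internal node is dated to the oldest FAD among its descendant tips
#' (the youngest dating consistent with the observed record); tips keep
#' their FAD.
#'
#' @param phy a rooted topology (`phylo`; branch lengths ignored).
#' @param fads named FAD vector (Ma) or taxon age table.
#' @return numeric vector of minimal ages over all nodes.
#' @export
node_min_ages <- function(phy, fads) {
  fads <- as_fad_vector(fads)
  f <- check_fads(phy, fads)
  n <- length(phy$tip.label)
  m <- c(unname(f), rep(-Inf, phy$Nnode))
  pr <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(pr$edge)))
    m[pr$edge[i, 1L]] <- max(m[pr$edge[i, 1L]], m[pr$edge[i, 2L]])
  m
}

#' Minimum implied gap (MIG)
#'
#' Total ghost range implied by a topology under minimal node dating: the
#' sum over non-root branches of parent minimal age minus child minimal age,
#' in myr. Lower is better.
#'
#' @inheritParams node_min_ages
#' @return MIG in myr (>= 0).
#' @export
mig <- function(phy, fads) {
  if (length(phy$tip.label) < 2L) stop("MIG needs at least 2 tips")
  m <- node_min_ages(phy, fads)
  sum(m[phy$edge[, 1L]] - m[phy$edge[, 2L]])
}

#' Per-branch ghost ranges under minimal dating
#' @inheritParams node_min_ages
#' @return numeric vector, one ghost range per edge (same order as
#'   `phy$edge`); sums to [mig()].
#' @export
ghost_ranges <- function(phy, fads) {
  m <- node_min_ages(phy, fads)
  m[phy$edge[, 1L]] - m[phy$edge[, 2L]]
}

#' Closed-form extremes of MIG over all rooted topologies
#'
#' `g_min = max(FAD) - min(FAD)` (attained by the age-ordered pectinate
#' tree) and `g_max = sum(max(FAD) - FAD)` (every taxon attached directly to
#' the oldest); both equal the exact extremes found by topology enumeration.
#'
#' @param fads named FAD vector or taxon age table.
#' @return named numeric vector `c(g_min, g_max)`.
#' @export
g_min_max <- function(fads) {
  f <- as_fad_vector(fads)
  if (length(f) < 2L) stop("need at least 2 taxa")
  c(g_min = max(f) - min(f), g_max = sum(max(f) - f))
}

#' Gap excess ratio (GER)
#'
#' `1 - (MIG - g_min) / (g_max - g_min)`; 1 is the best attainable
#' stratigraphic fit, 0 the worst. When `g_max == g_min` (e.g. two taxa, or
#' all FADs equal) the ratio is undefined and `NA` is returned with a
#' `reason` attribute rather than a silent 0 or 1.
#'
#' @inheritParams node_min_ages
#' @return GER in `[0, 1]`, or flagged `NA`.
#' @export
ger <- function(phy, fads) {
  fads <- as_fad_vector(fads)
  f <- check_fads(phy, fads)
  g <- g_min_max(f)
  if (g[["g_max"]] <= g[["g_min"]])
    return(structure(NA_real_, reason = "degenerate_normalizer"))
  unname(1 - (mig(phy, f) - g[["g_min"]]) / (g[["g_max"]] - g[["g_min"]]))
}

#' Stratigraphic consistency index (SCI)
#'
#' The proportion of non-root internal nodes whose clade's oldest FAD is not
#' older than the oldest FAD of its sister clade(s) (ties consistent; the
#' root has no sister and is excluded). For a polytomy the sister set is the
#' union of all other children of the parent.
#'
#' @inheritParams node_min_ages
#' @return SCI in `[0, 1]`.
#' @export
sci <- function(phy, fads) {
  fads <- as_fad_vector(fads)
  f <- check_fads(phy, fads)
  n <- length(phy$tip.label)
  m <- node_min_ages(phy, f)
  root <- n + 1L
  nodes <- setdiff(unique(phy$edge[, 2L]), seq_len(n))
  if (!length(nodes)) stop("no assessable (non-root internal) nodes")
  ok <- vapply(nodes, function(v) {
    p <- phy$edge[phy$edge[, 2L] == v, 1L]
    sibs <- phy$edge[phy$edge[, 1L] == p & phy$edge[, 2L] != v, 2L]
    m[v] <= max(m[sibs])
  }, logical(1))
  mean(ok)
}

#' Congruence metrics for every tree in a sample
#'
#' Applies [mig()], [sci()] and [ger()] to each tree. With
#' `fad_resampling = "uniform"` each replicate redraws every taxon's FAD
#' uniformly inside its stratigraphic interval (sensitivity analysis for the
#' point-FAD convention); `"off"` uses the interval's old bound.
#'
#' @param sample a [tree_sample()].
#' @param ages taxon age table (data frame `taxon`, `max_ma`, `min_ma`) or
#'   named FAD vector.
#' @param fad_resampling `"off"` or `"uniform"`.
#' @param n_reps replicates per tree when resampling.
#' @param seed integer seed (resampling only).
#' @return data frame with columns `tree_index`, `replicate`, `MIG`, `SCI`,
#'   `GER`, `g_min`, `g_max`, `ger_reason`.
#' @export
congruence_over_sample <- function(sample, ages, fad_resampling = c("off", "uniform"),
                                   n_reps = 1L, seed = 1L) {
  fad_resampling <- match.arg(fad_resampling)
  if (fad_resampling == "off") n_reps <- 1L
  draw_fads <- function() {
    if (fad_resampling == "off") return(as_fad_vector(ages))
    stopifnot(is.data.frame(ages))
    setNames(runif(nrow(ages), ages$min_ma, ages$max_ma), ages$taxon)
  }
  rows <- list()
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      f <- draw_fads()
      for (i in seq_along(sample)) {
        phy <- sample[[i]]
        g <- g_min_max(f[phy$tip.label])
        gv <- ger(phy, f)
        rows[[length(rows) + 1L]] <- data.frame(
          tree_index = i, replicate = r,
          MIG = mig(phy, f), SCI = sci(phy, f), GER = as.numeric(gv),
          g_min = g[["g_min"]], g_max = g[["g_max"]],
          ger_reason = if (is.na(gv)) attr(gv, "reason") else "")
      }
    }
  })
  do.call(rbind, rows)
}

## ---- enumeration oracle -------------------------------------------------

.topo_cache <- new.env(parent = emptyenv())

insert_leaf_everywhere <- function(tr, bit) {
  res <- list(list(bit, tr))
  if (is.list(tr)) {
    for (L in insert_leaf_everywhere(tr[[1L]], bit))
      res[[length(res) + 1L]] <- list(L, tr[[2L]])
    for (R in insert_leaf_everywhere(tr[[2L]], bit))
      res[[length(res) + 1L]] <- list(tr[[1L]], R)
  }
  res
}

collect_internal_masks <- function(tr, acc) {
  if (!is.list(tr)) return(list(mask = tr, acc = acc))
  a <- collect_internal_masks(tr[[1L]], acc)
  b <- collect_internal_masks(tr[[2L]], a$acc)
  m <- bitwOr(a$mask, b$mask)
  list(mask = m, acc = c(b$acc, m))
}

#' Internal clade bitmasks of every rooted binary topology
#'
#' Enumerates all `(2n-3)!!` rooted binary topologies on `n` labelled tips
#' and returns, per topology, the bitmasks of its `n - 1` internal clades
#' (taxon `i` contributes bit `2^(i-1)`). Cached per `n`.
#'
#' @param n number of tips, `2 <= n <= 9`.
#' @return integer matrix, one row per topology.
#' @export
enumerate_rooted_topologies <- function(n) {
  stopifnot(n >= 2, n <= 9)
  key <- as.character(n)
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  trees <- list(1L)
  for (i in 2:n) {
    bit <- bitwShiftL(1L, i - 1L)
    out <- vector("list", length(trees) * (2L * (i - 1L) - 1L))
    k <- 0L
    for (tr in trees) for (ins in insert_leaf_everywhere(tr, bit)) {
      k <- k + 1L; out[[k]] <- ins
    }
    trees <- out
  }
  M <- matrix(0L, length(trees), n - 1L)
  for (i in seq_along(trees))
    M[i, ] <- collect_internal_masks(trees[[i]], integer(0))$acc
  .topo_cache[[key]] <- M
  M
}

# max FAD over every non-empty taxon subset, indexed by bitmask
mask_max_fad <- function(fads) {
  n <- length(fads)
  out <- numeric(2^n - 1L)
  for (m in seq_len(2^n - 1L)) {
    low <- ffs(m)
    rest <- m - bitwShiftL(1L, low - 1L)
    out[m] <- if (rest == 0L) fads[low] else max(fads[low], out[rest])
  }
  out
}

ffs <- function(m) {
  i <- 1L
  while (bitwAnd(m, 1L) == 0L) { m <- bitwShiftR(m, 1L); i <- i + 1L }
  i
}

#' MIG of every rooted binary topology (enumeration)
#'
#' Exact MIG for all topologies on the given taxa, via the identity
#' MIG = sum over internal nodes of the clade's oldest FAD, minus the sum of
#' all FADs, plus the overall oldest FAD.
#'
#' @param fads FAD vector (order defines the bit assignment).
#' @return numeric vector of MIG values, one per topology.
#' @export
mig_all_topologies <- function(fads) {
  fads <- as_fad_vector(if (is.null(names(fads)))
    setNames(fads, paste0("x", seq_along(fads))) else fads)
  n <- length(fads)
  M <- enumerate_rooted_topologies(n)
  lk <- mask_max_fad(unname(fads))
  rowSums(matrix(lk[M], nrow(M), ncol(M))) - sum(fads) + max(fads)
}

#' Exact MIG extremes by exhaustive topology enumeration
#'
#' Test oracle for [g_min_max()]: scans all rooted binary topologies.
#'
#' @param fads FAD vector, at most 9 taxa.
#' @return named numeric vector `c(min, max)`.
#' @export
brute_force_extremes <- function(fads) {
  v <- mig_all_topologies(fads)
  c(min = min(v), max = max(v))
}
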