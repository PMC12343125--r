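## Summaries of posterior tree distributions: clade (split) frequencies,
## majority-rule consensus, maximum clade credibility (MCC) tree, splitwise
## phylogenetic information content, and greedy rogue-taxon detection.
##
## The trees are rooted, dated posteriors, so support is counted over rooted
## clades; information content is computed on the corresponding unrooted
## bipartitions, whose probability under a uniform tree distribution has the
## closed double-factorial form.

# log (2k-3)!! , the number of rooted binary trees on k labelled tips
log_dfact <- function(k) lfactorial(2 * k - 2) - (k - 1) * log(2) - lfactorial(k - 1)

#' Splitwise phylogenetic information content of one split (bits)
#'
#' `h(s) = -log2 P(s)` where `P(s) = (2a-3)!!(2b-3)!!/(2n-5)!!` is the
#' fraction of unrooted binary trees on `n` leaves containing the split with
#' side sizes `a` and `b`. Rare (large-vs-large) splits carry more
#' information than splits shaving off a couple of taxa. Trivial splits
#' (singleton side) are present in every tree and carry 0 bits.
#'
#' @param split a 0/1 split key (see [tree_splits()]) or the size of one
#'   side.
#' @param n_taxa leafset size (required when `split` is a side size).
#' @return bits (>= 0), with attribute `trivial = TRUE` for trivial splits.
#' @export
split_information <- function(split, n_taxa = NULL) {
  if (is.character(split)) {
    sides <- split_sides(split)
    a <- sides[1L]; n_taxa <- sum(sides)
  } else a <- split
  stopifnot(!is.null(n_taxa), n_taxa >= 4L, a >= 1L, a <= n_taxa - 1L)
  b <- n_taxa - a
  if (a < 2L || b < 2L) return(structure(0, trivial = TRUE))
  h <- -(log_dfact(a) + log_dfact(b) - log_dfact(n_taxa - 1L)) / log(2)
  max(0, h)
}

# per-tree non-root internal clades as logical matrices (rows = clades)
clade_bool_list <- function(sample, taxa = attr(sample, "leafset")) {
  if (is.null(taxa)) taxa <- sort(sample[[1L]]$tip.label)
  lapply(sample, function(phy) {
    n <- length(phy$tip.label)
    M <- clade_matrix(phy, taxa)
    root <- n + 1L
    ints <- setdiff(seq_len(n + phy$Nnode), c(seq_len(n), root))
    keep <- vapply(ints, function(v) sum(M[v, ]) >= 2L, logical(1))
    unique(M[ints[keep], , drop = FALSE])
  })
}

count_clades <- function(bool_list) {
  keys <- unlist(lapply(bool_list, function(M)
    apply(M, 1L, mask_key)), use.names = FALSE)
  table(keys)
}

#' Clade (split) frequencies in a tree sample
#'
#' Frequency of each observed non-trivial rooted clade: trees containing it
#' divided by the sample size. The information content of the corresponding
#' bipartition is reported alongside.
#'
#' @param sample a [tree_sample()].
#' @return data frame (`split`, `count`, `p`, `h`) sorted by decreasing `p`.
#' @export
split_frequencies <- function(sample) {
  if (length(sample) == 0L) stop("empty sample")
  taxa <- attr(sample, "leafset")
  tab <- count_clades(clade_bool_list(sample, taxa))
  keys <- names(tab)
  h <- vapply(keys, function(k) {
    s <- split_sides(k)
    as.numeric(split_information(min(s[1L], sum(s) - 1L), sum(s)))
  }, numeric(1))
  out <- data.frame(split = keys, count = as.integer(tab),
                    p = as.integer(tab) / length(sample), h = h,
                    row.names = NULL)
  out[order(-out$p, out$split), ]
}

# rooted tree from a set of pairwise-compatible clades (logical matrix)
build_rooted_from_clades <- function(clades, taxa) {
  n <- length(taxa)
  units <- c(lapply(seq_len(n), function(i) { v <- rep(FALSE, n); v[i] <- TRUE; v }),
             if (nrow(clades)) lapply(seq_len(nrow(clades)), function(i) clades[i, ]),
             list(rep(TRUE, n)))
  sizes <- vapply(units, sum, numeric(1))
  nu <- length(units)
  parent <- integer(nu)
  for (i in seq_len(nu - 1L)) {
    cont <- which(vapply(seq_len(nu), function(j)
      j != i && sizes[j] > sizes[i] && all(units[[j]] | !units[[i]]),
      logical(1)))
    parent[i] <- cont[which.min(sizes[cont])]
  }
  int_ids <- (n + 1L):nu
  int_ids <- c(nu, setdiff(int_ids, nu))       # root first
  num <- integer(nu)
  num[seq_len(n)] <- seq_len(n)
  num[int_ids] <- n + seq_along(int_ids)
  E <- cbind(num[parent[-nu]], num[seq_len(nu - 1L)])
  phy <- structure(list(edge = E, edge.length = rep(1, nrow(E)),
                        tip.label = taxa, Nnode = length(int_ids)),
                   class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy, "cladewise")
}

#' Majority-rule consensus of a tree sample
#'
#' Contains exactly the clades appearing in more than `threshold` of the
#' trees (strict majority guarantees pairwise compatibility). Node count and
#' per-clade support and information content are reported.
#'
#' @param sample a [tree_sample()].
#' @param threshold support threshold, >= 0.5.
#' @return object of class `consensus_tree`: list with `tree` (`phylo`,
#'   possibly polytomous), `supports` (data frame `split`, `p`, `h`),
#'   `n_nodes` (resolved non-root internal nodes), `n_taxa`.
#' @export
majority_rule_consensus <- function(sample, threshold = 0.5) {
  if (threshold < 0.5)
    stop("threshold below 0.5 no longer guarantees compatible splits")
  taxa <- attr(sample, "leafset")
  if (is.null(taxa)) taxa <- sort(sample[[1L]]$tip.label)
  sf <- split_frequencies(sample)
  keep <- sf[sf$p > threshold, , drop = FALSE]
  clades <- if (nrow(keep))
    t(vapply(keep$split, function(k) split_bits(k), logical(length(taxa))))
  else matrix(FALSE, 0L, length(taxa))
  tree <- build_rooted_from_clades(clades, taxa)
  structure(list(tree = tree,
                 supports = data.frame(split = keep$split, p = keep$p,
                                       h = keep$h, row.names = NULL),
                 n_nodes = nrow(keep), n_taxa = length(taxa),
                 threshold = threshold),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat("Majority-rule consensus (p > ", x$threshold, "): ", x$n_nodes,
      " resolved non-root nodes over ", x$n_taxa, " taxa\n", sep = "")
  invisible(x)
}

#' Maximum clade credibility tree of a sample
#'
#' Scores every sampled tree by its clades' posterior frequencies and
#' returns the best one (ties broken by earliest sample index), together
#' with the sum of posterior probabilities over its internal nodes.
#'
#' @param sample a [tree_sample()].
#' @param rule `"product"` (sum of log clade frequencies, the default) or
#'   `"sum"` (sum of frequencies); tools differ, so both are available and
#'   the choice is recorded in the result.
#' @return list with `tree`, `index`, `score`, `sum_posteriors`, `rule`.
#' @export
mcc_tree <- function(sample, rule = c("product", "sum")) {
  rule <- match.arg(rule)
  if (length(sample) == 0L) stop("empty sample")
  taxa <- attr(sample, "leafset")
  bl <- clade_bool_list(sample, taxa)
  tab <- count_clades(bl)
  p <- as.numeric(tab) / length(sample)
  names(p) <- names(tab)
  scores <- vapply(bl, function(M) {
    keys <- apply(M, 1L, mask_key)
    if (rule == "product") sum(log(p[keys])) else sum(p[keys])
  }, numeric(1))
  idx <- which.max(scores)    # which.max takes the earliest maximum
  keys <- apply(bl[[idx]], 1L, mask_key)
  list(tree = sample[[idx]], index = idx, score = scores[idx],
       sum_posteriors = sum(p[keys]) + 1,   # + root clade (p = 1)
       rule = rule)
}

#' Information content of a consensus tree (bits)
#'
#' `"plain"`: the sum of `h(s)` over the consensus' resolved splits -- the
#' information the topology would carry if asserted outright.
#' `"support_weighted"`: `sum(max(0, p*h(s) - H2(p)))`, discounting each
#' split by the uncertainty of its support `p` (`H2` = binary entropy), so a
#' barely-majority split contributes little. The mode is recorded in the
#' result; `support_weighted <= plain` always.
#'
#' @param consensus a [majority_rule_consensus()] result.
#' @param mode `"plain"` or `"support_weighted"`.
#' @return bits, with attribute `mode`.
#' @export
consensus_information <- function(consensus, mode = c("plain", "support_weighted")) {
  mode <- match.arg(mode)
  s <- consensus$supports
  if (nrow(s) == 0L) return(structure(0, mode = mode))
  # the two root-child clades are one unrooted bipartition: count it once,
  # at the larger of the two supports
  canon <- vapply(s$split, function(k) {
    b <- split_bits(k)
    if (!b[1L]) b <- !b
    mask_key(b)
  }, character(1))
  o <- order(canon, -s$p)
  s <- s[o, , drop = FALSE]; canon <- canon[o]
  s <- s[!duplicated(canon), , drop = FALSE]
  val <- switch(mode,
    plain = sum(s$h),
    support_weighted = {
      H2 <- function(p) ifelse(p <= 0 | p >= 1, 0,
                               -p * log2(p) - (1 - p) * log2(1 - p))
      sum(pmax(0, s$p * s$h - H2(s$p)))
    })
  structure(val, mode = mode)
}

# majority-rule information of a sample given per-tree clade matrices,
# restricted to the taxa in `keep` (logical over the column order); clades
# are projected onto the kept taxa and counted as canonical unrooted
# bipartitions so the root split is not counted twice
reduced_consensus_info <- function(bool_list, keep, mode) {
  n_keep <- sum(keep)
  n_trees <- length(bool_list)
  red <- lapply(bool_list, function(M) {
    R <- M[, keep, drop = FALSE]
    sz <- rowSums(R)
    R <- R[sz >= 2L & sz <= n_keep - 2L, , drop = FALSE]
    if (nrow(R)) {
      flip <- !R[, 1L]
      R[flip, ] <- !R[flip, , drop = FALSE]
    }
    unique(R)
  })
  tab <- count_clades(red)
  p <- as.integer(tab) / n_trees
  maj <- which(p > 0.5)
  if (!length(maj)) return(0)
  hs <- vapply(names(tab)[maj], function(k) {
    a <- split_sides(k)[1L]
    as.numeric(split_information(min(a, n_keep - a), n_keep))
  }, numeric(1))
  if (mode == "plain") return(sum(hs))
  H2 <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log2(q) - (1 - q) * log2(1 - q))
  sum(pmax(0, p[maj] * hs - H2(p[maj])))
}

#' Greedy rogue-taxon detection
#'
#' A rogue is a leaf whose unstable position degrades the consensus:
#' dropping it increases the consensus information content. The search is
#' greedy single-taxon: at each step the candidate whose removal gives the
#' largest strictly positive information gain is removed (ties broken by
#' label order); the loop stops when no removal helps or fewer than 5 taxa
#' would remain.
#'
#' @param sample a [tree_sample()] on at least 5 taxa.
#' @param mode information mode passed to [consensus_information()].
#' @return list with `rogues` (removal order), `gains` (bits, all > 0),
#'   `mean_improvement`, `initial_information`, `final_information`, and
#'   `final_consensus` on the reduced leafset.
#' @export
detect_rogues <- function(sample, mode = c("support_weighted", "plain")) {
  mode <- match.arg(mode)
  taxa <- attr(sample, "leafset")
  if (is.null(taxa)) taxa <- sort(sample[[1L]]$tip.label)
  if (length(taxa) < 5L) stop("rogue detection needs at least 5 taxa")
  bl <- clade_bool_list(sample, taxa)
  keep <- rep(TRUE, length(taxa))
  cur <- reduced_consensus_info(bl, keep, mode)
  initial <- cur
  rogues <- character(0); gains <- numeric(0)
  while (sum(keep) > 5L) {
    cand <- which(keep)
    info <- vapply(cand, function(i) {
      k2 <- keep; k2[i] <- FALSE
      reduced_consensus_info(bl, k2, mode)
    }, numeric(1))
    best <- which.max(info)   # earliest (label-order) maximum
    if (info[best] <= cur + 1e-12) break
    gains <- c(gains, info[best] - cur)
    rogues <- c(rogues, taxa[cand[best]])
    keep[cand[best]] <- FALSE
    cur <- info[best]
  }
  reduced <- tree_sample(lapply(sample, ape::keep.tip, tip = taxa[keep]))
  final_cons <- majority_rule_consensus(reduced)
  list(rogues = rogues, gains = gains,
       mean_improvement = if (length(gains)) mean(gains) else 0,
       initial_information = initial, final_information = cur,
       final_consensus = final_cons, mode = mode)
}

#' Full consensus report for one posterior sample
#'
#' Bundles the Table-1-style summary quantities: majority-rule node count,
#' rogue count and mean improvement, consensus information content, and the
#' MCC tree's sum of clade posterior probabilities.
#'
#' @param sample a [tree_sample()].
#' @param mode information mode.
#' @return list of class `consensus_report`.
#' @export
consensus_report <- function(sample, mode = c("support_weighted", "plain")) {
  mode <- match.arg(mode)
  cons <- majority_rule_consensus(sample)
  rog <- detect_rogues(sample, mode)
  mcc <- mcc_tree(sample)
  structure(list(
    n_nodes = cons$n_nodes,
    n_rogues = length(rog$rogues),
    information_content = as.numeric(consensus_information(cons, mode)),
    mean_improvement = rog$mean_improvement,
    sum_posteriors_mcc = mcc$sum_posteriors,
    consensus = cons, rogues = rog, mcc = mcc, mode = mode),
    class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("Consensus report (", x$mode, " information)\n", sep = "")
  cat("  N nodes (majority rule):        ", x$n_nodes, "\n")
  cat("  N rogues:                       ", x$n_rogues, "\n")
  cat("  information content (bits):     ", round(x$information_content, 2), "\n")
  cat("  mean improvement per rogue:     ", round(x$mean_improvement, 2), "\n")
  cat("  sum of posteriors (MCC tree):   ", round(x$sum_posteriors_mcc, 2), "\n")
  invisible(x)
}
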