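#' @keywords internal
"_PACKAGE"

#' @importFrom stats rexp runif rgamma rnorm rpois setNames var dist ecdf
#'   wilcox.test p.adjust quantile median
#' @importFrom utils head tail read.csv write.csv
#' @importFrom grDevices chull hcl.colors
#' @importFrom graphics axis boxplot image legend lines mtext par points
#'   segments text
NULL

## ---- reproducible substreams -------------------------------------------

#' Derive a named substream seed from a master seed
#'
#' All randomness in the package flows from one master seed; each stage draws
#' its own substream so that adding a stage never perturbs another stage's
#' stream. The derived seed is always a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param name character scalar naming the stage.
#' @return a single integer seed.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  s <- (abs(master) %% 2147483647) * 48271 + h
  as.integer(s %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- node ages ----------------------------------------------------------

node_depths <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  d <- numeric(nn)
  pr <- ape::reorder.phylo(phy, "postorder")
  root <- pr$edge[nrow(pr$edge), 1L]
  # preorder: walk edges in reverse postorder
  for (i in rev(seq_len(nrow(pr$edge)))) {
    p <- pr$edge[i, 1L]; ch <- pr$edge[i, 2L]
    d[ch] <- d[p] + pr$edge.length[i]
  }
  d
}

#' Node ages of a dated tree
#'
#' Ages are in Ma before the present; time increases into the past. When the
#' tree carries a `root.age` attribute (set by the simulator and by
#' [read_trees()] when an age table anchors the tips) ages are measured from
#' it; otherwise the deepest tip is placed at age 0 (contemporaneous-tip
#' assumption).
#'
#' @param phy an `ape::phylo` with branch lengths in myr.
#' @return numeric vector of ages indexed like the tree's internal node
#'   numbering (tips first, then internal nodes).
#' @export
node_ages <- function(phy) {
  d <- node_depths(phy)
  ra <- attr(phy, "root.age")
  if (is.null(ra)) ra <- max(d[seq_along(phy$tip.label)])
  a <- ra - d
  # zap numeric dust so age invariants survive round-trips
  a[abs(a) < 1e-12] <- 0
  a
}

#' Rewrite branch lengths from a vector of node ages
#'
#' @param phy an `ape::phylo`.
#' @param ages ages for all nodes, indexed as in [node_ages()].
#' @return the tree with `edge.length` recomputed as parent age minus child
#'   age and its `root.age` attribute set.
#' @export
set_node_ages <- function(phy, ages) {
  if (any(ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]] < -1e-9))
    stop("age vector violates parent age >= child age")
  phy$edge.length <- pmax(0, ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]])
  attr(phy, "root.age") <- ages[length(phy$tip.label) + 1L]
  phy
}

root_age <- function(phy) node_ages(phy)[length(phy$tip.label) + 1L]

#' Tip ages of a dated tree
#' @param phy an `ape::phylo`.
#' @return named numeric vector of tip ages (Ma).
#' @export
tip_ages <- function(phy) {
  a <- node_ages(phy)[seq_along(phy$tip.label)]
  names(a) <- phy$tip.label
  a
}

## ---- tree sample container ---------------------------------------------

#' Bundle trees sharing one leafset into a tree sample
#'
#' A tree sample is an ordered collection of dated trees over a single
#' leafset, standing for a posterior (or posterior-like) tree distribution.
#'
#' @param trees a list of `phylo` objects or a `multiPhylo`.
#' @param source optional provenance string.
#' @return an object of class `c("tree_sample", "multiPhylo")`.
#' @export
tree_sample <- function(trees, source = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("empty tree sample")
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tree ", i, " does not share the sample leafset")
  }
  structure(trees, class = c("tree_sample", "multiPhylo"),
            leafset = ref, source = source)
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample: ", length(x), " dated trees over ",
      length(attr(x, "leafset")), " taxa\n", sep = "")
  invisible(x)
}

#' @export
`[.tree_sample` <- function(x, i) {
  tree_sample(unclass(x)[i], source = attr(x, "source"))
}

## ---- splits and clades --------------------------------------------------

#' Logical clade matrix of a tree
#'
#' Row `v` flags the tips descending from node `v`, with columns in the order
#' of `taxa` (defaults to the sorted tip labels).
#' @keywords internal
clade_matrix <- function(phy, taxa = sort(phy$tip.label)) {
  n <- length(phy$tip.label)
  M <- matrix(FALSE, n + phy$Nnode, length(taxa))
  M[cbind(seq_len(n), match(phy$tip.label, taxa))] <- TRUE
  pr <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(pr$edge)))
    M[pr$edge[i, 1L], ] <- M[pr$edge[i, 1L], ] | M[pr$edge[i, 2L], ]
  M
}

mask_key <- function(x) paste(as.integer(x), collapse = "")

#' Non-trivial rooted clades of a tree
#'
#' @param phy an `ape::phylo`.
#' @param taxa column order for the clade encoding.
#' @return character vector of 0/1 clade keys, one per non-root internal node
#'   (clades of size >= 2, excluding the root clade).
#' @export
tree_clades <- function(phy, taxa = sort(phy$tip.label)) {
  n <- length(phy$tip.label)
  M <- clade_matrix(phy, taxa)
  root <- n + 1L
  ints <- setdiff(seq_len(n + phy$Nnode), c(seq_len(n), root))
  keys <- vapply(ints, function(v) mask_key(M[v, ]), character(1))
  keys[vapply(ints, function(v) sum(M[v, ]) >= 2L, logical(1))]
}

#' Canonical non-trivial bipartitions (splits) of a tree
#'
#' Trees are treated as unrooted: each internal edge induces one bipartition,
#' oriented so that the side containing the first taxon (in the `taxa` order)
#' is encoded as 1s. Splits with a singleton side are trivial and dropped;
#' duplicates from the two root-adjacent edges are merged.
#'
#' @inheritParams tree_clades
#' @return character vector of canonical split keys.
#' @export
tree_splits <- function(phy, taxa = sort(phy$tip.label)) {
  n <- length(phy$tip.label)
  M <- clade_matrix(phy, taxa)
  root <- n + 1L
  nodes <- setdiff(seq_len(n + phy$Nnode), c(seq_len(n), root))
  keys <- character(0)
  for (v in nodes) {
    side <- M[v, ]
    a <- sum(side)
    if (a < 2L || a > length(taxa) - 2L) next
    if (!side[1L]) side <- !side
    keys <- c(keys, mask_key(side))
  }
  unique(keys)
}

split_sides <- function(key) {
  bits <- as.integer(strsplit(key, "", fixed = TRUE)[[1L]])
  c(sum(bits), length(bits) - sum(bits))
}
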