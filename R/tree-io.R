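## Reading, writing, pruning and subsampling dated trees. Branch lengths are
## durations in myr; ages are Ma before present and need not be zero at the
## tips (fossil tips). When no tip dates are supplied the deepest tip is
## taken as contemporaneous (age 0).

#' Read a sample of dated trees
#'
#' @param path Newick or NEXUS file (NEXUS translate tables are resolved).
#' @param format `"newick"` or `"nexus"`.
#' @param ages optional taxon age table (data frame `taxon`, `max_ma`,
#'   `min_ma`) or named age vector anchoring tip ages; where branch lengths
#'   and the table disagree beyond 1e-6 myr the table wins for tips and a
#'   warning is issued.
#' @param burnin leading fraction of trees to drop before any analysis
#'   (default 0: the file is taken as already post-burnin).
#' @return a [tree_sample()].
#' @export
read_trees <- function(path, format = c("newick", "nexus"), ages = NULL,
                       burnin = 0) {
  format <- match.arg(format)
  trees <- switch(format,
                  newick = ape::read.tree(path),
                  nexus = ape::read.nexus(path))
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tree ", i, " has a different leafset from tree 1")
  if (burnin > 0) {
    drop <- floor(burnin * length(trees))
    if (drop >= length(trees)) stop("burn-in removes every tree")
    trees <- trees[(drop + 1L):length(trees)]
  }
  if (!is.null(ages)) {
    tipage <- if (is.data.frame(ages)) as_fad_vector(ages) else ages
    trees <- lapply(trees, anchor_tip_ages, tipage = tipage)
  }
  tree_sample(trees, source = path)
}

anchor_tip_ages <- function(phy, tipage) {
  miss <- setdiff(phy$tip.label, names(tipage))
  if (length(miss))
    stop("age table lacks taxa: ", paste(miss, collapse = ", "))
  d <- node_depths(phy)
  nt <- length(phy$tip.label)
  ta <- unname(tipage[phy$tip.label])
  pend <- vapply(seq_len(nt), function(i)
    phy$edge.length[phy$edge[, 2L] == i], numeric(1))
  # root age consistent with most tips; raised if a pendant edge would
  # otherwise need a negative duration
  ra <- max(median(ta + d[seq_len(nt)]), max(ta + d[seq_len(nt)] - pend))
  adj <- (ra - d[seq_len(nt)]) - ta
  if (any(abs(adj) > 1e-6))
    warning("tip ages adjusted to the age table (max discrepancy ",
            signif(max(abs(adj)), 3), " myr)")
  for (i in seq_len(nt)) {
    e <- which(phy$edge[, 2L] == i)
    phy$edge.length[e] <- phy$edge.length[e] + adj[i]
  }
  attr(phy, "root.age") <- ra
  phy
}

#' Write a tree sample to Newick or NEXUS
#'
#' @param sample a [tree_sample()] or `phylo`.
#' @param path output file.
#' @param format `"newick"` or `"nexus"` (NEXUS gets a translate table).
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_trees <- function(sample, path, format = c("newick", "nexus"),
                        digits = 12L) {
  format <- match.arg(format)
  if (inherits(sample, "phylo")) sample <- list(sample)
  mp <- structure(unclass(sample), class = "multiPhylo")
  if (format == "newick") {
    ape::write.tree(mp, file = path, digits = digits)
    return(invisible(path))
  }
  # NEXUS with a translate table, written at full precision
  taxa <- sort(mp[[1L]]$tip.label)
  lines <- c("#NEXUS", "BEGIN TREES;", "\tTRANSLATE",
             paste0("\t\t", seq_along(taxa), " ", taxa,
                    c(rep(",", length(taxa) - 1L), ";")))
  for (i in seq_along(mp)) {
    tr <- mp[[i]]
    tr$tip.label <- as.character(match(tr$tip.label, taxa))
    lines <- c(lines, paste0("\tTREE tree_", i, " = [&R] ",
                             ape::write.tree(tr, digits = digits)))
  }
  writeLines(c(lines, "END;"), path)
  invisible(path)
}

#' Prune a dated tree to a subset of taxa
#'
#' Keeps the minimal spanning subtree of the named tips, suppressing
#' degree-2 nodes by summing durations. All retained node ages -- in
#' particular the MRCA age of every kept taxon pair -- are unchanged.
#'
#' @param phy a dated `phylo`.
#' @param keep taxa to keep (subset of the leafset, at least 2).
#' @return the pruned dated tree.
#' @export
prune_to_leafset <- function(phy, keep) {
  miss <- setdiff(keep, phy$tip.label)
  if (length(miss))
    stop("taxa not in tree: ", paste(miss, collapse = ", "))
  if (length(keep) < 2L) stop("keep at least 2 taxa")
  ages <- node_ages(phy)
  mrca <- if (length(keep) == length(phy$tip.label)) length(phy$tip.label) + 1L
          else ape::getMRCA(phy, keep)
  out <- ape::keep.tip(phy, keep)
  attr(out, "root.age") <- ages[mrca]
  out
}

#' Uniformly subsample a tree sample without replacement
#'
#' @param sample a [tree_sample()].
#' @param fraction fraction in `(0, 1]` of trees to keep (rounded), or
#' @param count exact number of trees to keep (overrides `fraction`).
#' @param seed integer seed.
#' @return a [tree_sample()] preserving the original order.
#' @export
subsample_trees <- function(sample, fraction = NULL, count = NULL, seed = 1L) {
  n <- length(sample)
  size <- if (!is.null(count)) as.integer(count)
          else if (!is.null(fraction)) as.integer(round(fraction * n))
          else stop("give fraction or count")
  if (size < 1L || size > n)
    stop("requested ", size, " trees from a sample of ", n)
  idx <- with_seed(seed, sort(sample.int(n, size)))
  sample[idx]
}

#' Export genus monophyly constraints
#'
#' Writes (a) a NEXUS sets block of per-genus taxsets and (b) a JSON bundle
#' listing each monophyly constraint with its member taxa and per-taxon age
#' intervals. A genus is only a usable constraint if at least one member of
#' that genus has morphological information; genera violating this are
#' rejected.
#'
#' @param genus_map named character vector taxon -> genus.
#' @param ages taxon age table (data frame `taxon`, `max_ma`, `min_ma`).
#' @param morph_taxa taxa flagged as having morphology.
#' @param path base output path (writes `<path>.nex` and `<path>.json`).
#' @return the constraint list, invisibly.
#' @export
export_constraints <- function(genus_map, ages, morph_taxa, path) {
  miss <- setdiff(names(genus_map), ages$taxon)
  if (length(miss))
    stop("age table lacks taxa: ", paste(miss, collapse = ", "))
  genera <- split(names(genus_map), genus_map)
  bad <- names(genera)[!vapply(genera, function(tx)
    any(tx %in% morph_taxa), logical(1))]
  if (length(bad))
    stop("genus ", paste(bad, collapse = ", "), " violates the rule: ",
         "at least one member of that genus having morphological information")
  cons <- lapply(names(genera), function(g) {
    tx <- sort(genera[[g]])
    list(genus = g, taxa = tx,
         has_morphology = tx %in% morph_taxa,
         intervals = lapply(tx, function(t) {
           i <- match(t, ages$taxon)
           list(taxon = t, max_ma = ages$max_ma[i], min_ma = ages$min_ma[i])
         }))
  })
  names(cons) <- names(genera)
  nex <- c("#NEXUS", "BEGIN SETS;")
  for (g in names(genera))
    nex <- c(nex, paste0("  TAXSET ", g, " = ",
                         paste(sort(genera[[g]]), collapse = " "), ";"))
  nex <- c(nex, "END;")
  writeLines(nex, paste0(path, ".nex"))
  jsonlite::write_json(cons, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(cons)
}
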