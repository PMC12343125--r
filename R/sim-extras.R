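## Synthetic-data companions to the FBD simulator: a symmetric k-state
## morphological matrix, abundance-biased selection of the morphology taxon
## set, stage-binning of occurrence ages on a synthetic timescale, and a
## posterior-like tree sample generator standing in for MCMC output.

#' Simulate a symmetric k-state character matrix on a dated tree
#'
#' Characters evolve independently under a symmetric Markov model with `k`
#' states whose total leaving rate is 1 (so for two states the probability
#' that the endpoints of a path of length `t` differ is `(1 - exp(-2 t)) / 2`).
#' Per-character rate multipliers are drawn from a mean-1 gamma distribution;
#' `gamma_shape = Inf` fixes all multipliers at 1.
#'
#' @param tree a dated `phylo`.
#' @param n_chars number of characters (>= 1).
#' @param n_states number of states `k` (>= 2).
#' @param gamma_shape shape of the mean-1 gamma rate distribution.
#' @param missing_frac fraction of cells masked as missing, in `[0, 1]`.
#' @param seed integer seed.
#' @param rates optional explicit per-character rate multipliers (overrides
#'   the gamma draw; used e.g. to force invariant characters).
#' @return integer matrix (taxa x characters, states `0..k-1`, `NA` =
#'   missing) with the rate multipliers in `attr(, "rates")`.
#' @export
simulate_characters <- function(tree, n_chars, n_states = 2L,
                                gamma_shape = 1, missing_frac = 0,
                                seed = 1L, rates = NULL) {
  if (is.null(tree)) stop("empty tree")
  stopifnot(n_chars >= 1, n_states >= 2,
            missing_frac >= 0, missing_frac <= 1)
  k <- n_states
  with_seed(seed, {
    if (is.null(rates))
      rates <- if (is.finite(gamma_shape))
        rgamma(n_chars, shape = gamma_shape, rate = gamma_shape)
      else rep(1, n_chars)
    n <- length(tree$tip.label)
    states <- matrix(NA_integer_, n + tree$Nnode, n_chars)
    states[n + 1L, ] <- sample.int(k, n_chars, replace = TRUE) - 1L
    pr <- ape::reorder.phylo(tree, "postorder")
    for (i in rev(seq_len(nrow(pr$edge)))) {   # preorder
      p <- pr$edge[i, 1L]; ch <- pr$edge[i, 2L]
      t <- pr$edge.length[i]
      p_stay <- 1 / k + (1 - 1 / k) * exp(-k * rates * t / (k - 1))
      chg <- runif(n_chars) > p_stay
      s <- states[p, ]
      if (any(chg)) {
        shift <- sample.int(k - 1L, sum(chg), replace = TRUE)
        s[chg] <- (s[chg] + shift) %% k
      }
      states[ch, ] <- s
    }
    m <- states[seq_len(n), , drop = FALSE]
    rownames(m) <- tree$tip.label
    if (missing_frac > 0) {
      mask <- runif(length(m)) < missing_frac
      m[mask] <- NA_integer_
    }
    attr(m, "rates") <- rates
    m
  })
}

#' Write a character matrix as CSV with "?" for missing cells
#' @param m matrix from [simulate_characters()].
#' @param path output file.
#' @export
write_character_matrix <- function(m, path) {
  out <- apply(m, 2L, function(col) ifelse(is.na(col), "?", as.character(col)))
  out <- as.data.frame(out)
  rownames(out) <- rownames(m)
  write.csv(out, path, row.names = TRUE)
  invisible(path)
}

#' Select the morphology taxon set with abundance bias
#'
#' Emulates the practice of scoring morphology for the most abundantly
#' sampled taxa: draws `k` taxa without replacement with probability
#' proportional to (occurrence count)^`beta`. `beta = 0` recovers uniform
#' sampling; large `beta` concentrates on the most-sampled taxa. This biased
#' selection is what breaks the FBD assumption of uniform fossil sampling in
#' the morphology-only arm.
#'
#' @param occurrences occurrence table with a `taxon` column.
#' @param k number of taxa to select.
#' @param beta abundance-bias exponent, >= 0.
#' @param seed integer seed.
#' @return character vector of selected taxa.
#' @export
select_morph_taxa <- function(occurrences, k, beta = 1, seed = 1L) {
  stopifnot(beta >= 0)
  counts <- table(occurrences$taxon)
  if (k > length(counts))
    stop("k = ", k, " exceeds the ", length(counts), " distinct sampled taxa")
  with_seed(seed, {
    w <- as.numeric(counts)^beta
    sample(names(counts), k, prob = w)
  })
}

#' Build a stage timescale from ordered boundaries
#'
#' @param boundaries stage boundary ages in Ma, will be sorted oldest-first;
#'   consecutive boundaries delimit stages.
#' @return data frame (`stage`, `max_ma`, `min_ma`), oldest stage first.
#' @export
timescale <- function(boundaries) {
  b <- sort(unique(boundaries), decreasing = TRUE)
  if (length(b) < 2L) stop("need at least two boundaries")
  data.frame(stage = paste0("S", seq_len(length(b) - 1L)),
             max_ma = b[-length(b)], min_ma = b[-1L])
}

#' Bin occurrence ages into timescale stages
#'
#' Each occurrence's interval becomes the boundaries of the stage containing
#' its true age (an age exactly on a boundary binning to the older stage).
#' With probability `p_coarse` the interval is widened to a run of adjacent
#' stages, simulating imprecise stratigraphic records; the true age always
#' stays inside the reported interval.
#'
#' @param occurrences occurrence table with a `true_ma` column.
#' @param scale a [timescale()] data frame.
#' @param p_coarse probability of widening an interval, in `[0, 1]`.
#' @param coarse_stages number of extra stages added when widening (split at
#'   random between the two sides); `Inf` widens to the full timescale.
#' @param seed integer seed.
#' @return the occurrence table with `max_ma`/`min_ma` replaced by stage
#'   bounds.
#' @export
bin_occurrence_ages <- function(occurrences, scale, p_coarse = 0,
                                coarse_stages = 2L, seed = 1L) {
  stopifnot(p_coarse >= 0, p_coarse <= 1)
  ages <- occurrences$true_ma
  if (is.null(ages)) stop("occurrence table lacks a true_ma column")
  top <- scale$max_ma[1L]; bot <- scale$min_ma[nrow(scale)]
  bad <- which(ages > top | ages < bot)
  if (length(bad))
    stop("occurrence ", occurrences$occurrence_id[bad[1L]],
         " has age ", ages[bad[1L]], " outside the timescale span [",
         bot, ", ", top, "]")
  with_seed(seed, {
    n_st <- nrow(scale)
    for (i in seq_along(ages)) {
      a <- ages[i]
      # stage s spans [min_ma, max_ma); a boundary age belongs to the older
      # stage (the one whose young bound it is)
      s <- if (a == top) 1L else
        which(a >= scale$min_ma & a < scale$max_ma)[1L]
      lo <- s; hi <- s
      if (p_coarse > 0 && runif(1L) < p_coarse) {
        if (is.infinite(coarse_stages)) { lo <- 1L; hi <- n_st } else {
          left <- sample.int(coarse_stages + 1L, 1L) - 1L
          lo <- max(1L, s - left)
          hi <- min(n_st, s + (coarse_stages - left))
        }
      }
      occurrences$max_ma[i] <- scale$max_ma[lo]
      occurrences$min_ma[i] <- scale$min_ma[hi]
    }
    occurrences
  })
}

## ---- pseudo-posterior ---------------------------------------------------

# one random rooted nearest-neighbour interchange (topology only)
rooted_nni <- function(phy) {
  n <- length(phy$tip.label)
  E <- phy$edge
  cand <- which(E[, 2L] > n)
  if (!length(cand)) return(phy)
  e <- cand[sample.int(length(cand), 1L)]
  p <- E[e, 1L]; cnode <- E[e, 2L]
  sibs <- E[E[, 1L] == p & E[, 2L] != cnode, 2L]
  s <- if (length(sibs) == 1L) sibs else sibs[sample.int(length(sibs), 1L)]
  kids <- E[E[, 1L] == cnode, 2L]
  x <- kids[sample.int(length(kids), 1L)]
  row_s <- which(E[, 1L] == p & E[, 2L] == s)
  row_x <- which(E[, 1L] == cnode & E[, 2L] == x)
  E[row_s, 2L] <- x
  E[row_x, 2L] <- s
  phy$edge <- E
  phy
}

# oldest descendant tip age below every node (postorder)
max_desc_tip_age <- function(phy, tipage) {
  n <- length(phy$tip.label)
  m <- c(tipage, rep(-Inf, phy$Nnode))
  pr <- ape::reorder.phylo(phy, "postorder")
  for (i in seq_len(nrow(pr$edge)))
    m[pr$edge[i, 1L]] <- max(m[pr$edge[i, 1L]], m[pr$edge[i, 2L]])
  m
}

#' Generate a posterior-like sample of dated trees around a true tree
#'
#' Stands in for Bayesian MCMC output. Each tree is the true tree perturbed
#' by `Poisson(nni_rate)` random rooted nearest-neighbour interchanges, with
#' multiplicative lognormal jitter (sd `age_jitter_sd` on the log scale)
#' applied to internal node ages root-to-tip and clamped so that every parent
#' is at least as old as its children and tips keep their sampled ages. When
#' `congruence_weight` (gamma) is positive, proposals are accepted with
#' probability `min(1, exp(-gamma * (MIG - MIG_true)))` -- proportional to
#' `exp(-gamma * MIG)` for any proposal less congruent than the true tree --
#' which emulates stratigraphic age information making incongruent regions
#' of treespace implausible; after `max_retries` rejections the most
#' congruent (lowest-MIG) proposal seen is kept.
#'
#' @param true_tree a dated `phylo`.
#' @param n_trees number of trees to generate.
#' @param nni_rate mean number of NNI moves per tree, >= 0.
#' @param age_jitter_sd lognormal sd of internal-age jitter, >= 0.
#' @param congruence_weight stratigraphic acceptance weight gamma, >= 0
#'   (per myr of implied gap).
#' @param ages taxon age table (data frame `taxon`, `max_ma`, `min_ma`) or a
#'   named FAD vector; required when `congruence_weight > 0`.
#' @param seed integer seed.
#' @param max_retries rejection cap per tree.
#' @return a [tree_sample()].
#' @export
generate_pseudo_posterior <- function(true_tree, n_trees, nni_rate = 1,
                                      age_jitter_sd = 0.05,
                                      congruence_weight = 0, ages = NULL,
                                      seed = 1L, max_retries = 100L) {
  stopifnot(n_trees >= 1, nni_rate >= 0, age_jitter_sd >= 0,
            congruence_weight >= 0)
  fads <- NULL
  if (congruence_weight > 0) {
    if (is.null(ages)) stop("congruence_weight > 0 requires a taxon age table")
    fads <- as_fad_vector(ages)
    mig_ref <- mig(true_tree, fads)
  }
  n <- length(true_tree$tip.label)
  ages0 <- node_ages(true_tree)
  tipage <- ages0[seq_len(n)]
  propose <- function() {
    phy <- true_tree
    for (i in seq_len(rpois(1L, nni_rate))) phy <- rooted_nni(phy)
    prop <- ages0
    if (age_jitter_sd > 0) {
      idx <- (n + 1L):(n + phy$Nnode)
      prop[idx] <- prop[idx] * exp(rnorm(length(idx), 0, age_jitter_sd))
    }
    lower <- max_desc_tip_age(phy, tipage)
    final <- prop
    pr <- ape::reorder.phylo(phy, "postorder")
    root <- pr$edge[nrow(pr$edge), 1L]
    final[root] <- max(prop[root], lower[root])
    for (i in rev(seq_len(nrow(pr$edge)))) {    # preorder: parents first
      ch <- pr$edge[i, 2L]
      if (ch <= n) next
      final[ch] <- min(max(prop[ch], lower[ch]), final[pr$edge[i, 1L]])
    }
    set_node_ages(phy, final)
  }
  with_seed(seed, {
    out <- vector("list", n_trees)
    for (j in seq_len(n_trees)) {
      if (is.null(fads)) { out[[j]] <- propose(); next }
      best <- NULL; best_mig <- Inf
      accepted <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- propose()
        m <- mig(cand, fads)
        if (m < best_mig) { best <- cand; best_mig <- m }
        if (runif(1L) <= exp(-congruence_weight * (m - mig_ref))) {
          out[[j]] <- cand; accepted <- TRUE; break
        }
      }
      if (!accepted) out[[j]] <- best
    }
    tree_sample(out, source = "generate_pseudo_posterior")
  })
}
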