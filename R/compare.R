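## Two-arm comparison of posterior tree distributions: a "resolved" arm
## (taxa with morphology alone) against a "semi-resolved" arm (morphology
## plus occurrence-only taxa placed by taxonomic constraints, pruned back to
## the shared leafset). Both arms are analysed on the identical leafset and
## equal subsample sizes; outputs mirror the usual congruence distributions,
## treespace, consensus analytics and HPD-width comparisons.

#' Highest posterior density interval
#'
#' The shortest contiguous window of order statistics containing
#' `ceiling(mass * n)` of the samples (earliest window on ties).
#'
#' @param samples numeric vector of at least 2 draws.
#' @param mass interval mass in `(0, 1)`, default 0.95.
#' @return object of class `hpd_interval`: list `lower`, `upper`, `mass`,
#'   `width`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 2L) stop("need at least 2 samples")
  stopifnot(mass > 0, mass < 1)
  x <- sort(samples)
  m <- ceiling(mass * n)
  widths <- x[m:n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)
  structure(list(lower = x[i], upper = x[i + m - 1L], mass = mass,
                 width = x[i + m - 1L] - x[i]),
            class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(format(100 * x$mass), "% HPD: [", format(x$lower), ", ",
      format(x$upper), "]  width ", format(x$width), "\n", sep = "")
  invisible(x)
}

#' Node-age HPD widths for the clades of a reference tree
#'
#' For each internal clade of the reference (typically the MCC tree), the
#' clade's age is collected across all sample trees containing it and the
#' HPD width of those ages is reported. Clades present in fewer than 2
#' trees are reported as missing with their containment count.
#'
#' @param sample a [tree_sample()] of dated trees.
#' @param reference a dated `phylo` whose clades are queried.
#' @param mass interval mass.
#' @return data frame (`clade`, `size`, `n_present`, `lower`, `upper`,
#'   `width`).
#' @export
node_age_hpds <- function(sample, reference, mass = 0.95) {
  taxa <- sort(reference$tip.label)
  n <- length(reference$tip.label)
  M <- clade_matrix(reference, taxa)
  ints <- (n + 1L):(n + reference$Nnode)
  ref_keys <- vapply(ints, function(v) mask_key(M[v, ]), character(1))
  ages_by_key <- lapply(ref_keys, function(k) numeric(0))
  names(ages_by_key) <- ref_keys
  for (phy in sample) {
    a <- node_ages(phy)
    nM <- clade_matrix(phy, taxa)
    np <- length(phy$tip.label)
    for (v in (np + 1L):(np + phy$Nnode)) {
      k <- mask_key(nM[v, ])
      if (!is.null(ages_by_key[[k]]))
        ages_by_key[[k]] <- c(ages_by_key[[k]], a[v])
    }
  }
  rows <- lapply(seq_along(ref_keys), function(i) {
    ag <- ages_by_key[[ref_keys[i]]]
    if (length(ag) < 2L)
      return(data.frame(clade = ref_keys[i], size = sum(M[ints[i], ]),
                        n_present = length(ag), lower = NA_real_,
                        upper = NA_real_, width = NA_real_))
    h <- hpd_interval(ag, mass)
    data.frame(clade = ref_keys[i], size = sum(M[ints[i], ]),
               n_present = length(ag), lower = h$lower, upper = h$upper,
               width = h$width)
  })
  do.call(rbind, rows)
}

#' Two-sided rank test between two metric distributions
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum), invariant to monotone
#' transforms of both samples.
#'
#' @param x,y numeric samples of size >= 5 each.
#' @return list `statistic` (U), `p_value`, `method`.
#' @export
compare_metric_distributions <- function(x, y) {
  if (length(x) < 5L || length(y) < 5L) stop("each sample needs >= 5 values")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = "two-sided Mann-Whitney U")
}

resolve_arm <- function(arm) {
  if (inherits(arm, "tree_sample")) return(arm)
  if (inherits(arm, "multiPhylo") || (is.list(arm) && inherits(arm[[1L]], "phylo")))
    return(tree_sample(arm))
  if (is.list(arm) && !is.null(arm$file))
    return(read_trees(arm$file, format = if (is.null(arm$format)) "newick"
                      else arm$format,
                      burnin = if (is.null(arm$burnin)) 0 else arm$burnin))
  stop("arm must be a tree_sample, a list of phylo, or list(file=, format=)")
}

#' Run the full resolved vs semi-resolved comparison
#'
#' Pipeline: prune the semi-resolved arm to the morphology leafset ->
#' equal-size subsample of both arms -> per-arm congruence metrics ->
#' between-arm rank tests per metric (Holm-adjusted alongside raw) -> joint
#' treespace with congruence landscape, per-arm density and spread
#' statistics -> per-arm consensus/rogue/MCC analytics -> origin (root age)
#' and node-age HPD widths with percent narrowing. Fully reproducible from
#' `(config, seed)`; all randomness flows from the master seed through named
#' substreams.
#'
#' @param config list with elements `resolved` and `semi` (each a
#'   [tree_sample()], list of `phylo`, or `list(file=, format=, burnin=)`),
#'   `ages` (taxon age table data frame or CSV path), `morph_taxa`
#'   (character; the shared leafset), and optionally `subsample_fraction`
#'   (default 0.01), `subsample_count` (overrides the fraction), `metric`
#'   (`"cid"` default or `"rf"`), `info_mode` (`"support_weighted"` default), and
#'   `hpd_mass` (default 0.95).
#' @param seed master integer seed.
#' @return object of class `fbd_comparison`.
#' @export
run_comparison <- function(config, seed = 1L) {
  cfg <- config
  arms <- list(resolved = resolve_arm(cfg$resolved),
               semi = resolve_arm(cfg$semi))
  ages <- if (is.character(cfg$ages)) read_age_table(cfg$ages) else cfg$ages
  morph <- cfg$morph_taxa
  if (is.null(morph)) morph <- attr(arms$resolved, "leafset")
  metric <- if (is.null(cfg$metric)) "cid" else cfg$metric
  info_mode <- if (is.null(cfg$info_mode)) "support_weighted" else cfg$info_mode
  hpd_mass <- if (is.null(cfg$hpd_mass)) 0.95 else cfg$hpd_mass

  # stage 1: identical leafset in both arms
  for (a in names(arms)) {
    if (!all(morph %in% attr(arms[[a]], "leafset")))
      stop("stage leafset: arm '", a, "' lacks morphology taxa ",
           paste(setdiff(morph, attr(arms[[a]], "leafset")), collapse = ", "))
    if (length(attr(arms[[a]], "leafset")) > length(morph))
      arms[[a]] <- tree_sample(lapply(arms[[a]], prune_to_leafset, keep = morph),
                               source = attr(arms[[a]], "source"))
  }
  miss <- setdiff(morph, ages$taxon)
  if (length(miss))
    stop("stage ages: missing ages for ", paste(miss, collapse = ", "))

  # stage 2: equal-size subsample
  size <- if (!is.null(cfg$subsample_count)) cfg$subsample_count else {
    frac <- if (is.null(cfg$subsample_fraction)) 0.01 else cfg$subsample_fraction
    max(1L, round(frac * min(lengths <- vapply(arms, length, integer(1)))))
  }
  if (any(vapply(arms, length, integer(1)) < size))
    stop("stage subsample: arms smaller than the requested subsample")
  arms <- list(
    resolved = subsample_trees(arms$resolved, count = size,
                               seed = substream_seed(seed, "subsample_resolved")),
    semi = subsample_trees(arms$semi, count = size,
                           seed = substream_seed(seed, "subsample_semi")))

  # stage 3: congruence
  fads <- as_fad_vector(ages)[morph]
  congr <- lapply(arms, congruence_over_sample, ages = fads)

  # stage 4: between-arm tests (raw + Holm)
  tests <- lapply(c(MIG = "MIG", GER = "GER", SCI = "SCI"), function(mm)
    compare_metric_distributions(congr$resolved[[mm]], congr$semi[[mm]]))
  praw <- vapply(tests, `[[`, numeric(1), "p_value")
  padj <- p.adjust(praw, method = "holm")
  for (i in seq_along(tests)) tests[[i]]$p_holm <- padj[i]

  # stage 5: joint treespace
  joint <- tree_sample(c(unclass(arms$resolved), unclass(arms$semi)))
  grp <- rep(c("resolved", "semi"), each = size)
  D <- tree_distance_matrix(joint, metric = metric)
  emb <- pcoa_embed(D, k = 3L, group = grp,
                    values = c(congr$resolved$MIG, congr$semi$MIG))
  land <- treespace_landscape(emb)
  dens <- tryCatch(treespace_density(emb), warning = function(w)
    suppressWarnings(treespace_density(emb)))
  spread <- spread_stats(D, group = grp)   # full-space, projection-free

  # stage 6: consensus / rogue / MCC analytics
  reports <- lapply(arms, consensus_report, mode = info_mode)

  # stage 7: HPD widths ("origin age" here = root age of each sampled tree)
  root_ages <- lapply(arms, function(s) vapply(s, root_age, numeric(1)))
  origin_hpd <- lapply(root_ages, hpd_interval, mass = hpd_mass)
  node_hpd <- lapply(names(arms), function(a)
    node_age_hpds(arms[[a]], reports[[a]]$mcc$tree, mass = hpd_mass))
  names(node_hpd) <- names(arms)
  pct_narrow <- function(res, semi) 100 * (1 - semi / res)
  mean_w <- vapply(node_hpd, function(d) mean(d$width, na.rm = TRUE), numeric(1))
  max_w <- vapply(node_hpd, function(d)
    if (all(is.na(d$width))) NA_real_ else max(d$width, na.rm = TRUE), numeric(1))
  narrowing <- list(
    origin = pct_narrow(origin_hpd$resolved$width, origin_hpd$semi$width),
    mean_node = pct_narrow(mean_w[["resolved"]], mean_w[["semi"]]))

  structure(list(
    seed = seed, n_trees_per_arm = size, leafset = morph, metric = metric,
    congruence = congr, tests = tests, embedding = emb, landscape = land,
    density = dens, spread = spread, reports = reports,
    origin_hpd = origin_hpd, node_hpd = node_hpd,
    max_node_hpd_width = max_w, mean_node_hpd_width = mean_w,
    percent_narrowing = narrowing),
    class = "fbd_comparison")
}

#' Serialize a comparison report as stable JSON
#'
#' Identical `(config, seed)` runs give byte-identical strings.
#'
#' @param x an `fbd_comparison`.
#' @param path optional file to write.
#' @return JSON string, invisibly when `path` is given.
#' @export
report_json <- function(x, path = NULL) {
  summ <- function(v) list(mean = mean(v, na.rm = TRUE),
                           median = median(v, na.rm = TRUE))
  rep1 <- function(r) list(n_nodes = r$n_nodes, n_rogues = r$n_rogues,
                           information_content = r$information_content,
                           mean_improvement = r$mean_improvement,
                           sum_posteriors_mcc = r$sum_posteriors_mcc)
  obj <- list(
    seed = x$seed, n_trees_per_arm = x$n_trees_per_arm,
    n_taxa = length(x$leafset), metric = x$metric,
    congruence = lapply(x$congruence, function(d)
      list(MIG = summ(d$MIG), GER = summ(d$GER), SCI = summ(d$SCI))),
    tests = lapply(x$tests, function(t)
      list(U = t$statistic, p = t$p_value, p_holm = t$p_holm)),
    spread = split(x$spread[, -1], x$spread$group),
    consensus = lapply(x$reports, rep1),
    origin_hpd = lapply(x$origin_hpd, function(h)
      list(lower = h$lower, upper = h$upper, width = h$width)),
    mean_node_hpd_width = as.list(x$mean_node_hpd_width),
    max_node_hpd_width = as.list(x$max_node_hpd_width),
    percent_narrowing = x$percent_narrowing)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.fbd_comparison <- function(x, ...) {
  cat("Resolved vs semi-resolved comparison: ", x$n_trees_per_arm,
      " trees per arm on ", length(x$leafset), " taxa\n", sep = "")
  for (m in names(x$tests))
    cat(sprintf("  %s: resolved %.3g vs semi %.3g (U = %.4g, p = %.3g)\n", m,
                mean(x$congruence$resolved[[m]], na.rm = TRUE),
                mean(x$congruence$semi[[m]], na.rm = TRUE),
                x$tests[[m]]$statistic, x$tests[[m]]$p_value))
  cat(sprintf("  origin-age 95%% HPD width: resolved %.3g, semi %.3g (%.1f%% narrower)\n",
              x$origin_hpd$resolved$width, x$origin_hpd$semi$width,
              x$percent_narrowing$origin))
  invisible(x)
}

#' @export
summary.fbd_comparison <- function(object, ...) {
  print(object)
  cat("\nConsensus analytics:\n")
  for (a in names(object$reports)) {
    r <- object$reports[[a]]
    cat(sprintf("  %-9s N nodes %d, N rogues %d, information %.2f bits, mean improvement %.2f, sum posteriors (MCC) %.2f\n",
                a, r$n_nodes, r$n_rogues, r$information_content,
                r$mean_improvement, r$sum_posteriors_mcc))
  }
  cat("\nTreespace spread:\n")
  print(object$spread, row.names = FALSE)
  invisible(object)
}

#' Plot a comparison report
#'
#' Panels: per-metric boxplots by arm, the treespace congruence landscape
#' with per-arm symbols, per-arm density contours, and node-age HPD widths.
#'
#' @param x an `fbd_comparison`.
#' @param which subset of panels (1:4).
#' @param ... ignored.
#' @export
plot.fbd_comparison <- function(x, which = 1:4, ...) {
  op <- par(mfrow = c(ceiling(length(which) / 2), min(2, length(which))),
            mar = c(4, 4, 2, 1))
  on.exit(par(op))
  if (1 %in% which) {
    dat <- rbind(cbind(arm = "resolved", x$congruence$resolved),
                 cbind(arm = "semi", x$congruence$semi))
    boxplot(MIG ~ arm, dat, main = "MIG (lower = better)", ylab = "myr")
  }
  if (2 %in% which) {
    pts <- embedding_xy(x$embedding)
    pal <- hcl.colors(64, "viridis")
    cuts <- cut(x$embedding$values, 64, labels = FALSE)
    image(x$landscape$x, x$landscape$y, x$landscape$z, col = pal,
          xlab = "PCo 1", ylab = "PCo 2", main = "Congruence landscape (MIG)")
    points(pts, pch = ifelse(x$embedding$group == "resolved", 21, 24),
           bg = pal[cuts], cex = 0.8)
    legend("topright", pch = c(21, 24), legend = c("resolved", "semi"),
           bty = "n")
  }
  if (3 %in% which) {
    pts <- embedding_xy(x$embedding)
    plot(pts, type = "n", xlab = "PCo 1", ylab = "PCo 2",
         main = "Treespace density")
    cols <- c(resolved = "#D55E00", semi = "#0072B2")
    for (g in names(x$density))
      graphics::contour(x$density[[g]], add = TRUE, col = cols[[g]],
                        drawlabels = FALSE)
    legend("topright", lty = 1, col = cols, legend = names(cols), bty = "n")
  }
  if (4 %in% which) {
    w1 <- sort(x$node_hpd$resolved$width)
    w2 <- sort(x$node_hpd$semi$width)
    plot(w1, seq_along(w1), pch = 16, col = "#D55E00",
         xlim = range(c(w1, w2), na.rm = TRUE),
         xlab = "node-age 95% HPD width (myr)", ylab = "node rank",
         main = "Divergence-time precision")
    points(w2, seq_along(w2), pch = 17, col = "#0072B2")
    legend("bottomright", pch = c(16, 17), col = c("#D55E00", "#0072B2"),
           legend = c("resolved", "semi"), bty = "n")
  }
  invisible(x)
}

#' Build a synthetic paired-arm configuration from one FBD truth
#'
#' Simulates one FBD clade, derives taxon ages from stage-binned
#' occurrences, and generates two pseudo-posterior arms over the same truth:
#' the "resolved" arm without stratigraphic weighting (`gamma_resolved`,
#' default 0) and the "semi-resolved" arm with congruence weighting
#' (`gamma_semi`), emulating the extra stratigraphic age information of
#' occurrence-only taxa tightening the posterior.
#'
#' @param params an [fbd_params()] truth specification.
#' @param n_taxa_min,n_taxa_max accepted sampled-taxon range (re-simulates
#'   under fresh substreams until satisfied).
#' @param n_trees trees per arm.
#' @param nni_rate,age_jitter_sd perturbation scales for both arms.
#' @param gamma_resolved,gamma_semi congruence weights per arm.
#' @param stage_myr synthetic stage duration (myr).
#' @param p_coarse probability of an imprecise (widened) occurrence interval.
#' @param seed master seed.
#' @return list with `config` (for [run_comparison()]), `truth` (the
#'   `fbd_sim`), and `ages`.
#' @export
synthetic_comparison <- function(params = fbd_params(0.12, 0.05, 0.25, 60,
                                                     rho = 0,
                                                     min_samples = 15),
                                 n_taxa_min = 15L, n_taxa_max = 40L,
                                 n_trees = 100L, nni_rate = 3,
                                 age_jitter_sd = 0.08, gamma_resolved = 0,
                                 gamma_semi = 5, stage_myr = 5,
                                 p_coarse = 0.15, seed = 1L) {
  sim <- NULL
  for (k in 1:200) {
    # runaway or under-conditioned candidates count as rejections
    cand <- tryCatch(
      simulate_fbd(params, seed = substream_seed(seed, paste0("truth", k))),
      error = function(e) NULL)
    if (!is.null(cand) && !is.null(cand$tree) &&
        nrow(cand$tips) >= n_taxa_min && nrow(cand$tips) <= n_taxa_max) {
      sim <- cand; break
    }
  }
  if (is.null(sim)) stop("no simulated clade hit the taxon-count window")
  sc <- timescale(seq(params$t_origin, 0, by = -stage_myr))
  occ <- bin_occurrence_ages(sim$occurrences, sc, p_coarse = p_coarse,
                             seed = substream_seed(seed, "bin"))
  # extant taxa have no fossil occurrence row; date them at the present
  ages <- one_occurrence_per_species(occ, seed = substream_seed(seed, "ages"))
  ext <- setdiff(sim$tips$taxon, ages$taxon)
  if (length(ext))
    ages <- rbind(ages, data.frame(taxon = ext, max_ma = 0, min_ma = 0, fad = 0))
  ages <- ages[match(sort(sim$tips$taxon), ages$taxon), ]
  arm <- function(gamma, name)
    generate_pseudo_posterior(sim$tree, n_trees = n_trees,
                              nni_rate = nni_rate,
                              age_jitter_sd = age_jitter_sd,
                              congruence_weight = gamma, ages = ages,
                              seed = substream_seed(seed, name))
  list(config = list(resolved = arm(gamma_resolved, "arm_resolved"),
                     semi = arm(gamma_semi, "arm_semi"),
                     ages = ages, morph_taxa = sort(sim$tips$taxon),
                     subsample_count = n_trees),
       truth = sim, ages = ages)
}
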