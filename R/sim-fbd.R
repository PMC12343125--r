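## Forward simulation of the fossilized birth-death (FBD) process.
##
## One lineage enters at the origin time and evolves with constant rates:
## speciation lambda, extinction mu, fossil recovery psi (all events /
## lineage / myr). Speciation is bifurcating: the parent species ends and two
## new species begin, so every edge of the complete tree is one species.
## Extant species are sampled with probability rho at the present.

#' Parameters of the constant-rate fossilized birth-death process
#'
#' @param lambda speciation rate (events/lineage/myr), >= 0.
#' @param mu extinction rate (events/lineage/myr), >= 0.
#' @param psi fossil recovery rate (samples/lineage/myr), >= 0.
#' @param t_origin origin age (Ma before present), > 0.
#' @param rho extant sampling probability in `[0, 1]`.
#' @param condition `"none"` or `"min_samples"` (retry until at least
#'   `min_samples` samples are retained).
#' @param min_samples minimum retained samples under conditioning.
#' @param max_attempts retry cap under conditioning.
#' @param max_lineages hard cap on the number of species in one history.
#' @return an object of class `fbd_params`.
#' @export
fbd_params <- function(lambda, mu, psi, t_origin, rho = 1,
                       condition = c("min_samples", "none"),
                       min_samples = 10L, max_attempts = 1000L,
                       max_lineages = 5000L) {
  condition <- match.arg(condition)
  stopifnot(lambda >= 0, mu >= 0, psi >= 0, t_origin > 0,
            rho >= 0, rho <= 1, min_samples >= 1, max_attempts >= 1,
            max_lineages >= 1)
  structure(list(lambda = lambda, mu = mu, psi = psi, t_origin = t_origin,
                 rho = rho, condition = condition,
                 min_samples = as.integer(min_samples),
                 max_attempts = as.integer(max_attempts),
                 max_lineages = as.integer(max_lineages)),
            class = "fbd_params")
}

# one unconditioned forward pass; returns species + fossil tables
sim_fbd_once <- function(p) {
  cap <- p$max_lineages
  sp_parent <- integer(cap); sp_birth <- numeric(cap); sp_end <- numeric(cap)
  sp_type <- character(cap)
  f_species <- integer(0); f_age <- numeric(0)
  total <- p$lambda + p$mu + p$psi
  stack_id <- 1L; stack_birth <- p$t_origin; stack_par <- 0L
  n_sp <- 0L; next_id <- 2L
  while (length(stack_id)) {
    id <- stack_id[1L]; birth <- stack_birth[1L]; par <- stack_par[1L]
    stack_id <- stack_id[-1L]; stack_birth <- stack_birth[-1L]
    stack_par <- stack_par[-1L]
    n_sp <- n_sp + 1L
    if (n_sp > cap) stop("FBD simulation exceeded max_lineages = ", cap)
    sp_parent[id] <- par; sp_birth[id] <- birth
    age <- birth
    repeat {
      nxt <- if (total > 0) age - rexp(1L, total) else -Inf
      if (nxt <= 0) { sp_end[id] <- 0; sp_type[id] <- "present"; break }
      u <- runif(1L) * total
      if (u < p$psi) {                       # fossil sample, lineage continues
        f_species <- c(f_species, id); f_age <- c(f_age, nxt)
        age <- nxt
      } else if (u < p$psi + p$mu) {         # extinction
        sp_end[id] <- nxt; sp_type[id] <- "extinction"; break
      } else {                               # bifurcating speciation
        sp_end[id] <- nxt; sp_type[id] <- "speciation"
        if (next_id + 1L > cap) stop("FBD simulation exceeded max_lineages = ", cap)
        stack_id <- c(stack_id, next_id, next_id + 1L)
        stack_birth <- c(stack_birth, nxt, nxt)
        stack_par <- c(stack_par, id, id)
        next_id <- next_id + 2L
        break
      }
    }
  }
  ids <- seq_len(next_id - 1L)
  list(species = data.frame(id = ids, parent = sp_parent[ids],
                            birth_age = sp_birth[ids], end_age = sp_end[ids],
                            end_type = sp_type[ids]),
       fossils = data.frame(species = f_species, age = f_age))
}

species_label <- function(id) sprintf("t%d", id)

# Reconstruct the minimal dated subtree spanning all retained samples.
# Returns list(tree = phylo or NULL, tips = data.frame(taxon, age, role)).
reconstruct_fbd <- function(species, fossils, extant_retained) {
  kids <- split(species$id, factor(species$parent, levels = species$id))
  samp_age <- vector("list", nrow(species))
  for (i in seq_len(nrow(fossils)))
    samp_age[[fossils$species[i]]] <- c(samp_age[[fossils$species[i]]],
                                        fossils$age[i])
  for (s in extant_retained) samp_age[[s]] <- c(samp_age[[s]], 0)

  nodes <- list()   # each: list(age, label or NULL, children = int ids)
  newn <- function(age, label = NULL, children = integer(0)) {
    nodes[[length(nodes) + 1L]] <<- list(age = age, label = label,
                                         children = children)
    length(nodes)
  }
  tips <- list()
  rec <- function(sid) {
    subs <- integer(0)
    for (d in kids[[as.character(sid)]]) {
      r <- rec(d)
      if (!is.na(r)) subs <- c(subs, r)
    }
    sa <- samp_age[[sid]]
    if (is.null(sa) && length(subs) == 0L) return(NA_integer_)
    if (is.null(sa)) {
      if (length(subs) == 1L) return(subs)
      return(newn(species$end_age[sid], children = subs))
    }
    t_obs <- min(sa)   # the species is observed down to its youngest sample
    role <- if (any(sa == 0)) "extant"
            else if (length(subs)) "sampled_ancestor" else "fossil"
    lab <- species_label(sid)
    tips[[length(tips) + 1L]] <<- data.frame(taxon = lab, age = t_obs,
                                             role = role)
    tip_id <- newn(t_obs, label = lab)
    if (length(subs) == 0L) return(tip_id)
    lower <- if (length(subs) == 1L) subs
             else newn(species$end_age[sid], children = subs)
    newn(t_obs, children = c(tip_id, lower))
  }
  root_rec <- rec(1L)
  tips <- if (length(tips)) do.call(rbind, tips) else
    data.frame(taxon = character(0), age = numeric(0), role = character(0))
  if (is.na(root_rec) || !is.null(nodes[[root_rec]]$label))
    return(list(tree = NULL, tips = tips,
                crown_age = if (is.na(root_rec)) NA_real_ else
                  nodes[[root_rec]]$age))
  list(tree = nodes_to_phylo(nodes, root_rec), tips = tips,
       crown_age = nodes[[root_rec]]$age)
}

nodes_to_phylo <- function(nodes, root) {
  is_tip <- vapply(nodes, function(z) !is.null(z$label), logical(1))
  tip_ids <- which(is_tip)
  int_ids <- c(root, setdiff(which(!is_tip), root))
  num <- integer(length(nodes))
  num[tip_ids] <- seq_along(tip_ids)
  num[int_ids] <- length(tip_ids) + seq_along(int_ids)
  E <- matrix(0L, 0L, 2L); len <- numeric(0)
  for (v in int_ids) for (ch in nodes[[v]]$children) {
    E <- rbind(E, c(num[v], num[ch]))
    len <- c(len, nodes[[v]]$age - nodes[[ch]]$age)
  }
  phy <- structure(list(edge = E, edge.length = pmax(0, len),
                        tip.label = vapply(nodes[tip_ids], `[[`, "", "label"),
                        Nnode = length(int_ids)),
                   class = "phylo", order = "cladewise")
  attr(phy, "root.age") <- nodes[[root]]$age
  phy
}

#' Simulate a clade under the fossilized birth-death process
#'
#' Simulates the complete history forward from one lineage at the origin,
#' places fossil samples by a Poisson process at rate `psi` along every alive
#' lineage, retains extant tips with probability `rho`, and reconstructs the
#' minimal dated subtree spanning the retained samples. Fossil samples on
#' lineages with later-sampled descendants are emitted as sampled ancestors
#' (zero-length pendant edges).
#'
#' @param params an [fbd_params()] object.
#' @param seed integer seed; identical `(params, seed)` give identical output.
#' @return an object of class `fbd_sim`: list with elements `params`,
#'   `species` (complete history), `fossils`, `tips` (taxon, age, role),
#'   `tree` (reconstructed `phylo`, or `NULL` when fewer than two taxa are
#'   sampled), `stem_length` (origin age minus reconstructed root age),
#'   `occurrences` (one row per fossil sample) and `attempts`.
#' @export
simulate_fbd <- function(params, seed = 1L) {
  stopifnot(inherits(params, "fbd_params"))
  with_seed(seed, {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      h <- sim_fbd_once(params)
      extant <- h$species$id[h$species$end_type == "present"]
      keep <- extant[runif(length(extant)) <= params$rho]
      n_samples <- nrow(h$fossils) + length(keep)
      if (params$condition == "none" || n_samples >= params$min_samples) break
      if (attempts >= params$max_attempts)
        stop("conditioning failed: min_samples = ", params$min_samples,
             " not reached in ", params$max_attempts, " attempts")
    }
    rc <- reconstruct_fbd(h$species, h$fossils, keep)
    n_occ <- nrow(h$fossils) + length(keep)
    ages_occ <- c(h$fossils$age, numeric(length(keep)))
    occ <- data.frame(
      occurrence_id = seq_len(n_occ),
      taxon = c(species_label(h$fossils$species), species_label(keep)),
      genus = rep(NA_character_, n_occ), rank = rep("species", n_occ),
      max_ma = ages_occ, min_ma = ages_occ, true_ma = ages_occ)
    structure(list(params = params, species = h$species, fossils = h$fossils,
                   extant_retained = keep, tips = rc$tips, tree = rc$tree,
                   stem_length = params$t_origin -
                     (if (is.na(rc$crown_age)) params$t_origin else rc$crown_age),
                   occurrences = occ, attempts = attempts, seed = seed),
              class = "fbd_sim")
  })
}

#' @export
print.fbd_sim <- function(x, ...) {
  cat("FBD simulation: ", nrow(x$species), " species in complete history; ",
      nrow(x$tips), " sampled taxa (",
      sum(x$tips$role == "extant"), " extant, ",
      sum(x$tips$role == "fossil"), " fossil tips, ",
      sum(x$tips$role == "sampled_ancestor"), " sampled ancestors); ",
      nrow(x$fossils), " fossil occurrences\n", sep = "")
  invisible(x)
}

#' Assign sampled taxa to genera by a stem-crossing rule
#'
#' Genera are the maximal clades of the true species tree whose stem edge
#' crosses the age `tau_genus`: a species' genus is the unique edge on its
#' root path spanning that level. A sampled species whose entire edge is
#' older than `tau_genus` forms its own singleton genus. Each genus is
#' monophyletic on the true tree by construction.
#'
#' @param history an `fbd_sim` object, or a list with a `species` data frame
#'   (`id`, `parent`, `birth_age`, `end_age`) and optionally `tips`.
#' @param tau_genus genus-defining age (Ma), strictly inside
#'   `(0, t_origin)`.
#' @param taxa taxa to map (defaults to the sampled tip labels).
#' @return named character vector mapping each taxon to a genus label.
#' @export
assign_genera <- function(history, tau_genus, taxa = NULL) {
  sp <- history$species
  t0 <- if (!is.null(history$params)) history$params$t_origin else
    max(sp$birth_age)
  if (!(tau_genus > 0 && tau_genus < t0))
    stop("tau_genus must lie strictly inside (0, t_origin)")
  if (is.null(taxa)) taxa <- history$tips$taxon
  ids <- as.integer(sub("^t", "", taxa))
  parent <- sp$parent[order(sp$id)]
  birth <- sp$birth_age[order(sp$id)]
  endd <- sp$end_age[order(sp$id)]
  genus_of <- function(id) {
    if (endd[id] > tau_genus) return(paste0("G", id, "s"))  # singleton, pre-tau
    cur <- id
    repeat {
      if (birth[cur] > tau_genus && endd[cur] <= tau_genus)
        return(paste0("G", cur))
      cur <- parent[cur]
      if (cur == 0L) return("G1")   # origin stem
    }
  }
  setNames(vapply(ids, genus_of, character(1)), taxa)
}
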