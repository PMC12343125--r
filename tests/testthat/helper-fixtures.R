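# Small fixtures shared across the suite; everything is built in code.

toy_tree <- function(text) ape::read.tree(text = text)

# random rooted topology with unit branch lengths (for topology-only metrics)
rand_topology <- function(n) {
  phy <- ape::rtree(n)
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy
}

# random dated ultrametric-ish tree (coalescent times)
rand_dated <- function(n) ape::rcoal(n)

# manual complete history: root at 12, speciation at 10, two clades
# originating at 6, four terminal species reaching the present.
balanced_history <- function() {
  list(params = list(t_origin = 12),
       species = data.frame(
         id = 1:7,
         parent = c(0L, 1L, 1L, 2L, 2L, 3L, 3L),
         birth_age = c(12, 10, 10, 6, 6, 6, 6),
         end_age = c(10, 6, 6, 0, 0, 0, 0),
         end_type = c("speciation", "speciation", "speciation",
                      "present", "present", "present", "present")),
       tips = data.frame(taxon = c("t4", "t5", "t6", "t7"),
                         age = 0, role = "extant"))
}

# age-ordered pectinate topology: oldest taxon attaches at the base
pectinate_tree <- function(fads) {
  ord <- names(sort(fads))            # youngest first
  txt <- ord[1L]
  for (t in ord[-1L]) txt <- paste0("(", txt, ",", t, ")")
  toy_tree(paste0(txt, ";"))
}

# tree sample in which taxon X hops to a random branch; all other
# relationships fixed
rogue_sample <- function(n_trees = 40, seed = 99) {
  base <- toy_tree("(((A,B),(C,D)),(E,F));")
  base$edge.length <- rep(1, nrow(base$edge))
  fbdstrata:::with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i) {
      node <- base$edge[sample.int(nrow(base$edge), 1L), 2L]
      phytools::bind.tip(base, "X", edge.length = 1, where = node,
                         position = 0.5)
    })
    tree_sample(trees)
  })
}

# same shape, shuffled labels (a topologically scrambled copy)
rand_relabel <- function(phy) {
  phy$tip.label <- sample(phy$tip.label)
  phy
}

toy_occurrences <- function() {
  data.frame(
    occurrence_id = 1:5,
    taxon = c("Aus bus", "Aus", "Cus dus", "Eus fus", "Gus hus"),
    genus = c("Aus", "Aus", "Cus", "Eus", "Gus"),
    rank = c("species", "genus", "species", "species", "species"),
    max_ma = c(100, 90, 140, 80, 70),
    min_ma = c(95, 85, 80, 75, 66))
}
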