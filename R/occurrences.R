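## Cleaning of PBDB-style occurrence tables and derivation of one
## stratigraphic age interval per species. Mirrors the usual preparation of
## occurrence data for tip dating: records not identified to species rank
## and records with very imprecise intervals are dropped, species already
## covered by the morphological matrix are excluded, and each remaining
## species receives the interval of one randomly chosen occurrence.

#' Read a PBDB-like occurrence CSV
#'
#' Accepts either native column names (`taxon`, `rank`) or PBDB export names
#' (`accepted_name`, `accepted_rank`).
#'
#' @param path CSV file.
#' @return occurrence data frame with columns `occurrence_id`, `taxon`,
#'   `genus`, `rank`, `max_ma`, `min_ma`.
#' @export
read_occurrences <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if ("accepted_name" %in% names(d)) names(d)[names(d) == "accepted_name"] <- "taxon"
  if ("accepted_rank" %in% names(d)) names(d)[names(d) == "accepted_rank"] <- "rank"
  if (!"occurrence_id" %in% names(d)) d$occurrence_id <- seq_len(nrow(d))
  if (!"genus" %in% names(d)) d$genus <- NA_character_
  need <- c("occurrence_id", "taxon", "genus", "rank", "max_ma", "min_ma")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("occurrence file lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(d$max_ma < d$min_ma)) stop("max_ma < min_ma in occurrence table")
  d[union(need, names(d))]
}

#' Write an occurrence table as CSV
#' @param occurrences occurrence data frame.
#' @param path output file.
#' @export
write_occurrences <- function(occurrences, path) {
  write.csv(occurrences, path, row.names = FALSE)
  invisible(path)
}

#' Clean an occurrence table
#'
#' Applies, in order: (1) drop records identified more coarsely than species
#' rank; (2) drop records whose stratigraphic interval is wider than
#' `max_interval_myr` (very imprecise records); (3) drop records of taxa in
#' `exclude` (typically the species already in the morphological matrix,
#' whose literature ages are higher-resolution). A record removed by several
#' rules is attributed to the first matching rule, so the audit counts are
#' deterministic and sum with the retained count to the input count.
#'
#' @param occurrences occurrence data frame.
#' @param max_interval_myr imprecision threshold in myr (default 15).
#' @param exclude taxa to drop.
#' @return list with `occurrences` (retained table) and `audit` (named
#'   removal counts: `rank`, `imprecise`, `excluded`).
#' @export
clean_occurrences <- function(occurrences, max_interval_myr = 15,
                              exclude = character(0)) {
  if (nrow(occurrences) == 0L)
    return(list(occurrences = occurrences,
                audit = c(rank = 0L, imprecise = 0L, excluded = 0L)))
  r1 <- occurrences$rank != "species"
  r2 <- !r1 & (occurrences$max_ma - occurrences$min_ma) > max_interval_myr
  r3 <- !r1 & !r2 & occurrences$taxon %in% exclude
  list(occurrences = occurrences[!(r1 | r2 | r3), , drop = FALSE],
       audit = c(rank = sum(r1), imprecise = sum(r2), excluded = sum(r3)))
}

#' Derive one age interval per species
#'
#' For each species exactly one occurrence is chosen uniformly at random and
#' its interval becomes the species' stratigraphic interval; the derived
#' point FAD defaults to the interval's old bound.
#'
#' @param occurrences cleaned occurrence data frame.
#' @param seed integer seed.
#' @return taxon age table: data frame (`taxon`, `max_ma`, `min_ma`, `fad`),
#'   one row per species, sorted by taxon.
#' @export
one_occurrence_per_species <- function(occurrences, seed = 1L) {
  taxa <- sort(unique(occurrences$taxon))
  with_seed(seed, {
    rows <- vapply(taxa, function(t) {
      i <- which(occurrences$taxon == t)
      if (length(i) > 1L) i <- i[sample.int(length(i), 1L)]
      i
    }, integer(1))
    data.frame(taxon = taxa,
               max_ma = occurrences$max_ma[rows],
               min_ma = occurrences$min_ma[rows],
               fad = occurrences$max_ma[rows],
               row.names = NULL)
  })
}

#' Read / write taxon age tables
#' @param path CSV file with columns `taxon`, `max_ma`, `min_ma`.
#' @return data frame (`taxon`, `max_ma`, `min_ma`, `fad`).
#' @export
read_age_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "max_ma", "min_ma") %in% names(d)))
  if (any(d$max_ma < d$min_ma)) stop("max_ma < min_ma in age table")
  if (!"fad" %in% names(d)) d$fad <- d$max_ma
  d
}

#' @rdname read_age_table
#' @param ages age table data frame.
#' @export
write_age_table <- function(ages, path) {
  write.csv(ages, path, row.names = FALSE)
  invisible(path)
}
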