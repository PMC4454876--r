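# Turning ortholog clusters into ortholog pair maps between each reference
# species and the target species.
#
# Each cluster spans the target species and exactly one reference species.
# Two mapping schemes mirror the two interactome constructions:
#   * seed pairs (one-to-one): the single best member per species — full
#     inparalog score (1.0) AND 100% bootstrap — one pair per cluster;
#   * expanded pairs (many-to-many): every cross combination of members,
#     letting inparalogs substitute for one another.

cluster_split <- function(clusters, target_species) {
  stopifnot(is.data.frame(clusters))
  sp <- unique(clusters$species_tag)
  if (!(target_species %in% sp) && nrow(clusters) > 0)
    stop_validation("target species '", target_species,
                    "' absent from cluster table")
  split(clusters, clusters$cluster_id)
}

#' Extract one-to-one seed ortholog pairs
#'
#' From each cluster, selects per species the member with inparalog score
#' 1.0 and bootstrap 100%, and emits the single (target, reference) seed
#' pair. Clusters where either species has no qualifying member yield no
#' pair and are counted as skipped. When several members qualify on a side,
#' the lexicographically smallest protein id (byte order) is chosen, so the
#' selection is deterministic.
#'
#' @param clusters An `ortholog_clusters` member table.
#' @param target_species Species tag of the target organism in the table.
#' @return An `ortholog_pairs` data frame with columns `target_protein`,
#'   `reference_protein`, `reference_species`, `cluster_id`, `scheme`
#'   (`"seed"`), and attribute `skipped` (number of clusters without a
#'   qualifying seed pair).
#' @export
seed_pairs <- function(clusters, target_species) {
  validate_clusters(as.data.frame(clusters))
  by_cluster <- cluster_split(clusters, target_species)
  rows <- vector("list", length(by_cluster))
  skipped <- 0L
  for (i in seq_along(by_cluster)) {
    cl <- by_cluster[[i]]
    qual <- cl[cl$inparalog_score == 1 & cl$bootstrap_percent == 100L, ,
               drop = FALSE]
    tgt <- qual$protein_id[qual$species_tag == target_species]
    ref <- qual$protein_id[qual$species_tag != target_species]
    if (length(tgt) == 0 || length(ref) == 0) {
      skipped <- skipped + 1L
      next
    }
    ref_sp <- unique(cl$species_tag[cl$species_tag != target_species])
    rows[[i]] <- data.frame(
      target_protein = byte_min(tgt),
      reference_protein = byte_min(ref),
      reference_species = ref_sp,
      cluster_id = cl$cluster_id[1],
      scheme = "seed",
      stringsAsFactors = FALSE)
  }
  out <- bind_pair_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

byte_min <- function(x) x[order(byte_key(x))][1]

bind_pair_rows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    data.frame(target_protein = character(0), reference_protein = character(0),
               reference_species = character(0), cluster_id = character(0),
               scheme = character(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

#' Expand clusters into all many-to-many ortholog pairs
#'
#' Emits every (target member x reference member) cross combination for
#' each cluster, so inparalogs on either side can substitute for one
#' another. The pair count per cluster is the product of the two member
#' counts; seed pairs are a subset by construction.
#'
#' @inheritParams seed_pairs
#' @return An `ortholog_pairs` data frame with `scheme = "expanded"`.
#' @export
expand_pairs <- function(clusters, target_species) {
  validate_clusters(as.data.frame(clusters))
  by_cluster <- cluster_split(clusters, target_species)
  rows <- lapply(by_cluster, function(cl) {
    tgt <- cl$protein_id[cl$species_tag == target_species]
    ref <- cl$protein_id[cl$species_tag != target_species]
    ref_sp <- unique(cl$species_tag[cl$species_tag != target_species])
    grid <- expand.grid(target_protein = tgt, reference_protein = ref,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$reference_species <- ref_sp
    grid$cluster_id <- cl$cluster_id[1]
    grid$scheme <- "expanded"
    grid
  })
  bind_pair_rows(rows)
}

#' Build an ortholog lookup map
#'
#' Indexes ortholog pairs by (reference species, reference protein) so that
#' interaction transfer can look up the set of target-species orthologs of
#' any reference protein in constant time. Values are unions over clusters;
#' the total mapped pair count is preserved.
#'
#' @param pairs An `ortholog_pairs` data frame from [seed_pairs()] or
#'   [expand_pairs()].
#' @return An `ortholog_map` object (environment-backed hash from
#'   species/protein key to a character vector of target proteins).
#' @export
ortholog_map <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  key <- paste(pairs$reference_species, pairs$reference_protein, sep = "\r")
  tgt <- split(pairs$target_protein, key)
  tgt <- lapply(tgt, unique)
  structure(list(map = list2env(tgt, parent = emptyenv()),
                 n_pairs = sum(lengths(tgt))),
            class = "ortholog_map")
}

omap_lookup <- function(omap, species, protein) {
  get0(paste(species, protein, sep = "\r"), envir = omap$map,
       inherits = FALSE)
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("ortholog_map:", length(ls(x$map)), "reference proteins,",
      x$n_pairs, "mapped pairs\n")
  invisible(x)
}
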