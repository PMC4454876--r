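# Undirected interaction network: construction, degree/hub census,
# degree distribution and power-law fit, characteristic path length,
# conserved subnetworks and bait-and-prey neighbourhoods.
#
# The graph is undirected with self-loops allowed. "Degree" throughout is
# the number of distinct interacting partners of a node, with a self-loop
# contributing one partner (the node itself) — not edge multiplicity.

#' Build an interaction network from predictions
#'
#' Creates an undirected `ppi_network` with one edge per predicted
#' interaction (canonical pairs, self-loops allowed); nodes are the union
#' of edge endpoints and edge attributes (CV, supporting-species count,
#' confidence bin) are carried along.
#'
#' @param predictions An `interolog_predictions` object or a data frame
#'   with columns `protein_a`, `protein_b` and optionally `cv`,
#'   `n_species`, `bin`.
#' @return A `ppi_network`: list with `edges` (data frame) and `nodes`
#'   (character vector).
#' @export
build_network <- function(predictions) {
  df <- if (inherits(predictions, "interolog_predictions"))
    predictions$predictions else as.data.frame(predictions)
  stopifnot(all(c("protein_a", "protein_b") %in% names(df)))
  edges <- data.frame(
    protein_a = df$protein_a, protein_b = df$protein_b,
    cv = if ("cv" %in% names(df)) df$cv else NA_integer_,
    n_species = if ("n_species" %in% names(df)) df$n_species else NA_integer_,
    bin = if ("bin" %in% names(df)) df$bin else NA_character_,
    stringsAsFactors = FALSE)
  if (anyDuplicated(pair_key(edges$protein_a, edges$protein_b)))
    stop_validation("duplicate canonical pairs; deduplicate predictions first")
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$protein_a, edges$protein_b)))),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "proteins,", nrow(x$edges),
      "interactions\n")
  invisible(x)
}

as_igraph <- function(network, loops = TRUE) {
  e <- network$edges
  if (!loops) e <- e[e$protein_a != e$protein_b, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = e[, c("protein_a", "protein_b")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
}

# Distinct-partner sets per node (self-loop adds the node itself once).
partner_sets <- function(network) {
  e <- network$edges
  adj <- lapply(stats::setNames(vector("list", length(network$nodes)),
                                network$nodes), function(x) character(0))
  for (i in seq_len(nrow(e))) {
    a <- e$protein_a[i]; b <- e$protein_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

#' Node degree (distinct interacting partners)
#'
#' The number of distinct partners of a node, counting a self-loop as one
#' partner (the node itself).
#'
#' @param network A `ppi_network`.
#' @param node Protein id(s); defaults to all nodes.
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(network, node = NULL) {
  deg <- lengths(partner_sets(network))
  if (is.null(node)) return(deg)
  unknown <- setdiff(node, names(deg))
  if (length(unknown) > 0)
    stop_validation("unknown node(s): ", paste(unknown, collapse = ", "))
  deg[node]
}

#' Hub classification of a degree
#'
#' Nodes with more than 10 partners are highly connected hubs, 3-10
#' partners small hubs, 2 partners pipes, 1 partner free ends, and 0
#' partners isolated.
#'
#' @param degree Non-negative integer vector.
#' @return Character vector of hub classes.
#' @export
classify_node <- function(degree) {
  if (any(degree < 0) || anyNA(degree)) stop_validation("degree must be >= 0")
  cut(degree, breaks = c(-0.5, 0.5, 1.5, 2.5, 10.5, Inf),
      labels = c("isolated", "free_end", "pipe", "small_hub",
                 "highly_connected_hub")) |> as.character()
}

#' Degree and hub class per node
#'
#' @param network A `ppi_network`.
#' @return Data frame with `protein`, `degree`, `hub_class`.
#' @export
node_stats <- function(network) {
  deg <- node_degree(network)
  data.frame(protein = names(deg), degree = as.integer(deg),
             hub_class = classify_node(deg), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Degree distribution and mean connectivity
#'
#' @param network A non-empty `ppi_network`.
#' @return A list: `histogram` (data frame degree/count), `mean_degree`.
#' @export
degree_distribution <- function(network) {
  if (length(network$nodes) == 0) stop_validation("empty network")
  deg <- node_degree(network)
  tab <- table(deg)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab), row.names = NULL)
  list(histogram = hist, mean_degree = mean(deg))
}

#' Log-log least-squares power-law fit of a degree histogram
#'
#' Fits an ordinary least-squares line to (log10 degree, log10 frequency)
#' over degrees >= 1 and reports the negated slope as the power-law
#' exponent, with the fit's R-squared. This is the transparent diagnostic
#' for the inverse power relationship between node frequency and
#' connectivity typical of small-world interactomes, not a maximum
#' likelihood estimator.
#'
#' @param histogram Data frame with columns `degree` and `count`.
#' @return A list: `exponent`, `r_squared`.
#' @export
fit_power_law <- function(histogram) {
  h <- histogram[histogram$degree >= 1 & histogram$count > 0, , drop = FALSE]
  if (nrow(h) < 3)
    stop_validation("need at least 3 nonzero-degree histogram bins")
  x <- log10(h$degree); y <- log10(h$count)
  slope <- stats::cov(x, y) / stats::var(x)
  resid <- y - (mean(y) + slope * (x - mean(x)))
  ss_tot <- sum((y - mean(y))^2)
  # a flat histogram has zero total variance: the constant fit is exact
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  list(exponent = -slope, r_squared = min(1, max(0, r2)))
}

#' Characteristic path length
#'
#' The mean shortest-path length over all unordered pairs of distinct,
#' mutually reachable nodes (self-loops are irrelevant to shortest paths;
#' unreachable pairs are excluded from the mean). Also returns the
#' path-length frequency histogram.
#'
#' @param network A `ppi_network` with at least 2 nodes.
#' @return A list: `cpl`, `histogram` (data frame length/count),
#'   `unreachable_pairs`.
#' @export
characteristic_path_length <- function(network) {
  if (length(network$nodes) < 2) stop_validation("need at least 2 nodes")
  g <- as_igraph(network, loops = FALSE)
  dt <- igraph::distance_table(g, directed = FALSE)
  counts <- dt$res
  if (sum(counts) == 0) stop_validation("no reachable node pair")
  lens <- seq_along(counts)
  list(cpl = sum(lens * counts) / sum(counts),
       histogram = data.frame(length = lens[counts > 0],
                              count = counts[counts > 0], row.names = NULL),
       unreachable_pairs = dt$unconnected)
}

#' Conserved subnetwork at a species threshold
#'
#' The subgraph of edges supported in at least `min_species` reference
#' species; nodes left isolated by the filter are dropped. The edge sets
#' are nested as the threshold grows.
#'
#' @param network A `ppi_network` whose edges carry `n_species`.
#' @param min_species Minimum supporting-species count per edge.
#' @return A `ppi_network`, with attribute `stats` (node count, edge
#'   count, mean edges per node).
#' @export
conserved_subnetwork <- function(network, min_species) {
  e <- network$edges[network$edges$n_species >= min_species, , drop = FALSE]
  rownames(e) <- NULL
  sub <- structure(list(edges = e,
                        nodes = sort(unique(c(e$protein_a, e$protein_b)))),
                   class = "ppi_network")
  attr(sub, "stats") <- c(nodes = length(sub$nodes), edges = nrow(e),
                          edges_per_node = if (length(sub$nodes) > 0)
                            nrow(e) / length(sub$nodes) else NA_real_)
  sub
}

#' Bait-and-prey first-neighbour subnetwork
#'
#' Given a bait protein set (typically chosen by a GO term such as
#' "response to other organism"), extracts the subnetwork induced by the
#' baits and their first neighbours. Prey are the neighbours that are not
#' themselves baits; bait-bait edges are retained; baits absent from the
#' network are counted as unmatched.
#'
#' @param network A `ppi_network`.
#' @param baits Non-empty character vector of bait protein ids.
#' @return A list: `subnetwork` (`ppi_network`), `prey` (character),
#'   `matched_baits`, `unmatched_baits`.
#' @export
bait_prey <- function(network, baits) {
  baits <- unique(as.character(baits))
  if (length(baits) == 0) stop_validation("bait set must be non-empty")
  matched <- intersect(baits, network$nodes)
  unmatched <- setdiff(baits, network$nodes)
  adj <- partner_sets(network)
  neigh <- unique(unlist(adj[matched], use.names = FALSE))
  keep_nodes <- union(matched, neigh)
  e <- network$edges
  keep <- e$protein_a %in% keep_nodes & e$protein_b %in% keep_nodes
  sub_e <- e[keep, , drop = FALSE]
  rownames(sub_e) <- NULL
  sub <- structure(list(edges = sub_e,
                        nodes = sort(unique(c(sub_e$protein_a,
                                              sub_e$protein_b)))),
                   class = "ppi_network")
  list(subnetwork = sub, prey = sort(setdiff(neigh, matched)),
       matched_baits = sort(matched), unmatched_baits = sort(unmatched))
}

#' Plain-text topology report
#'
#' @param network A `ppi_network`.
#' @return A list with node/edge counts, mean connectivity, hub-class
#'   census, characteristic path length and its histogram.
#' @export
topology_report <- function(network) {
  dd <- degree_distribution(network)
  ns <- node_stats(network)
  census <- table(factor(ns$hub_class,
                         levels = c("highly_connected_hub", "small_hub",
                                    "pipe", "free_end", "isolated")))
  cpl <- if (length(network$nodes) >= 2)
    characteristic_path_length(network) else NULL
  list(n_nodes = length(network$nodes), n_edges = nrow(network$edges),
       mean_connectivity = dd$mean_degree,
       degree_histogram = dd$histogram,
       hub_census = as.data.frame(census, responseName = "count",
                                  stringsAsFactors = FALSE) |>
         stats::setNames(c("hub_class", "count")),
       characteristic_path_length = if (is.null(cpl)) NA_real_ else cpl$cpl,
       path_length_histogram = if (is.null(cpl)) NULL else cpl$histogram)
}
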