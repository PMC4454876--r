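# Builders for tiny in-code fixtures and independent oracles.

member_row <- function(cid, sp, id, score = 1, boot = 100L) {
  data.frame(cluster_id = cid, species_tag = sp, protein_id = id,
             inparalog_score = score, bootstrap_percent = as.integer(boot),
             stringsAsFactors = FALSE)
}

# One two-species cluster; tgt/ref are lists of c(id, score, bootstrap).
make_cluster <- function(cid, tgt, ref, tgt_sp = "tgt", ref_sp = "ref01") {
  rows <- c(
    lapply(tgt, function(m) member_row(cid, tgt_sp, m[[1]],
                                       as.numeric(m[[2]]),
                                       as.integer(m[[3]]))),
    lapply(ref, function(m) member_row(cid, ref_sp, m[[1]],
                                       as.numeric(m[[2]]),
                                       as.integer(m[[3]]))))
  do.call(rbind, rows)
}

make_refs <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(species = r[[1]], id_a = r[[2]], id_b = r[[3]],
               method = if (length(r) > 3) r[[4]] else "y2h",
               source_db = if (length(r) > 4) r[[5]] else "DBX",
               publication = "", stringsAsFactors = FALSE)))
  class(out) <- c("reference_interactions", "data.frame")
  out
}

make_network <- function(a, b, n_species = NA_integer_, cv = NA_integer_) {
  cp <- canonical_pair(a, b)
  build_network(data.frame(protein_a = cp$protein_a,
                           protein_b = cp$protein_b,
                           cv = cv, n_species = n_species,
                           bin = NA_character_, stringsAsFactors = FALSE))
}

write_tsv_fixture <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# All-pairs BFS mean shortest path oracle over an undirected edge list
# (loops ignored), averaging over unordered reachable pairs of distinct
# nodes; independent of igraph.
bfs_cpl_oracle <- function(edges_a, edges_b, nodes) {
  adj <- lapply(setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_along(edges_a)) {
    a <- edges_a[i]; b <- edges_b[i]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  total <- 0; count <- 0
  hist <- integer(0)
  for (s in nodes) {
    dist <- setNames(rep(NA_integer_, length(nodes)), nodes)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    reach <- dist[names(dist) != s & !is.na(dist)]
    total <- total + sum(reach); count <- count + length(reach)
  }
  if (count == 0) return(NA_real_)
  total / count / 1  # ordered pairs; symmetric, so equal to unordered mean
}

# Exhaustive hypergeometric tail oracle by enumerating all C(bg, n) draws.
enum_hyper_tails <- function(bg, K, n) {
  # returns for each feasible observed x the inclusive upper/lower tail
  members <- seq_len(bg) <= K
  counts <- if (n == 0) 0L else colSums(matrix(members[utils::combn(bg, n)],
                                               nrow = n))
  xs <- max(0, n - (bg - K)):min(n, K)
  list(x = xs,
       upper = vapply(xs, function(x) mean(counts >= x), numeric(1)),
       lower = vapply(xs, function(x) mean(counts <= x), numeric(1)))
}

random_ids <- function(n, prefix = "PR") {
  sprintf("%s%05d_P%02d", prefix, sample.int(99999, n, replace = TRUE),
          sample.int(3, n, replace = TRUE))
}
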