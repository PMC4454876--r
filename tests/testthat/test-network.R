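test_that("network construction keeps self-loops and distinct endpoints", {
  loop <- make_network("a", "a")
  expect_equal(length(loop$nodes), 1)
  expect_equal(nrow(loop$edges), 1)

  net <- make_network(c("a", "b"), c("b", "c"))
  expect_equal(length(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)

  dup <- data.frame(protein_a = c("b", "b"), protein_b = c("a", "a"))
  expect_error(build_network(dup), "duplicate")
})

test_that("degree counts distinct partners with self-loops contributing one", {
  net <- make_network(c("a", "a", "a"), c("b", "c", "a"))
  expect_equal(unname(node_degree(net, "a")), 3L)  # partners {b, c, a}
  expect_equal(unname(node_degree(net, "b")), 1L)
  expect_error(node_degree(net, "zz"), "unknown")
})

test_that("hub classes follow the partner-count thresholds", {
  expect_equal(classify_node(c(11, 10, 3, 2, 1, 0)),
               c("highly_connected_hub", "small_hub", "small_hub", "pipe",
                 "free_end", "isolated"))
  expect_error(classify_node(-1), class = "interologr_validation_error")
})

test_that("degree distribution sums to the node count", {
  tri <- make_network(c("a", "b", "c"), c("b", "c", "a"))
  dd <- degree_distribution(tri)
  expect_equal(dd$histogram, data.frame(degree = 2L, count = 3L))
  expect_equal(dd$mean_degree, 2)

  star <- make_network(rep("hub", 4), paste0("leaf", 1:4))
  dd2 <- degree_distribution(star)
  expect_equal(dd2$histogram,
               data.frame(degree = c(1L, 4L), count = c(4L, 1L)))
  expect_equal(dd2$mean_degree, 1.6)

  # histogram total equals node count on a fixture network
  uni <- generate_universe(n_reference_species = 3, n_target_proteins = 30,
                           inparalog_rate = 0.4, seed = 81)
  pl <- plant_reference_interactions(
    uni, data.frame(S = c(1, 2), E = 1, multiplicity = 1, count = c(10, 10)),
    seed = 82)
  net <- build_network(predict_interactome(uni$clusters,
                                           pl$interactions)$predictions)
  dd3 <- degree_distribution(net)
  expect_equal(sum(dd3$histogram$count), length(net$nodes))
  expect_equal(dd3$histogram$count,
               as.integer(table(node_degree(net))))
})

test_that("power-law fit recovers exact and degenerate log-log lines", {
  k <- c(1, 2, 4, 8)
  exact <- data.frame(degree = k, count = 1000 * k^-2)
  fit <- fit_power_law(exact)
  expect_equal(fit$exponent, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- data.frame(degree = k, count = 7)
  expect_equal(fit_power_law(flat)$exponent, 0, tolerance = 1e-12)

  expect_error(fit_power_law(exact[1:2, ]), "3")

  g <- igraph::sample_pa(400, power = 1, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(g)
  cp <- canonical_pair(paste0("n", el[, 1]), paste0("n", el[, 2]))
  net <- build_network(unique(cp))
  fit2 <- fit_power_law(degree_distribution(net)$histogram)
  expect_gt(fit2$exponent, 0.5)  # inverse power relationship present
})

test_that("characteristic path length matches hand-computed means", {
  tri <- make_network(c("a", "b", "c"), c("b", "c", "a"))
  expect_equal(characteristic_path_length(tri)$cpl, 1)

  path <- make_network(c("a", "b"), c("b", "c"))
  expect_equal(characteristic_path_length(path)$cpl, 4 / 3)
})

test_that("characteristic path length equals the all-pairs BFS oracle", {
  set.seed(99)
  for (rep in 1:4) {
    n <- sample(10:40, 1)
    p <- stats::runif(1, 0.05, 0.3)
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < p
    if (sum(keep) < 2) next
    a <- paste0("v", idx[keep, 1]); b <- paste0("v", idx[keep, 2])
    cp <- unique(canonical_pair(a, b))
    net <- build_network(cp)
    got <- characteristic_path_length(net)
    oracle <- bfs_cpl_oracle(net$edges$protein_a, net$edges$protein_b,
                             net$nodes)
    expect_equal(got$cpl, oracle)
    expect_equal(sum(got$histogram$length * got$histogram$count) /
                   sum(got$histogram$count), got$cpl)
  }
})

test_that("conserved subnetworks are nested and drop isolated nodes", {
  net <- make_network(c("a", "b", "c"), c("b", "c", "d"),
                      n_species = c(1, 4, 5))
  empty <- conserved_subnetwork(make_network("a", "b", n_species = 1), 4)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(empty$nodes), 0)

  ident <- conserved_subnetwork(net, 0)
  expect_equal(ident$edges, net$edges)

  s4 <- conserved_subnetwork(net, 4)
  s5 <- conserved_subnetwork(net, 5)
  expect_equal(nrow(s4$edges), 2)
  expect_equal(nrow(s5$edges), 1)
  expect_true(all(paste(s5$edges$protein_a, s5$edges$protein_b) %in%
                    paste(s4$edges$protein_a, s4$edges$protein_b)))
  expect_false("a" %in% s4$nodes)  # isolated after filtering
})

test_that("bait-and-prey extracts the first-neighbour subnetwork", {
  star <- make_network(rep("hub", 4), paste0("leaf", 1:4))
  bp <- bait_prey(star, "hub")
  expect_length(bp$prey, 4)
  expect_equal(nrow(bp$subnetwork$edges), 4)

  two <- make_network("baitA", "baitB")
  bp2 <- bait_prey(two, c("baitA", "baitB"))
  expect_length(bp2$prey, 0)
  expect_equal(nrow(bp2$subnetwork$edges), 1)

  expect_error(bait_prey(star, character(0)), "non-empty")

  # fixture: brute-force neighbourhood oracle
  uni <- generate_universe(n_reference_species = 3, n_target_proteins = 30,
                           seed = 91)
  pl <- plant_reference_interactions(
    uni, data.frame(S = 2, E = 1, multiplicity = 1, count = 15), seed = 92)
  net <- build_network(predict_interactome(uni$clusters,
                                           pl$interactions)$predictions)
  baits <- utils::head(net$nodes, 5)
  bp3 <- bait_prey(net, c(baits, "not_in_network"))
  e <- net$edges
  nb <- unique(c(e$protein_b[e$protein_a %in% baits],
                 e$protein_a[e$protein_b %in% baits]))
  expect_setequal(bp3$prey, setdiff(nb, baits))
  expect_equal(bp3$unmatched_baits, "not_in_network")
})

test_that("topology report aggregates counts, census and path lengths", {
  net <- make_network(c("a", "b", "c"), c("b", "c", "a"))
  rep <- topology_report(net)
  expect_equal(rep$n_nodes, 3)
  expect_equal(rep$n_edges, 3)
  expect_equal(rep$mean_connectivity, 2)
  expect_equal(sum(rep$hub_census$count), 3)
  expect_equal(rep$characteristic_path_length, 1)
})
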