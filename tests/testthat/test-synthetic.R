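test_that("a zero-inparalog universe makes expanded equal seed pairs", {
  uni <- generate_universe(n_reference_species = 2, n_target_proteins = 20,
                           inparalog_rate = 0, bootstrap_fail_rate = 0,
                           seed = 1)
  sp <- seed_pairs(uni$clusters, uni$target_species)
  ep <- expand_pairs(uni$clusters, uni$target_species)
  expect_equal(nrow(sp), nrow(ep))
  expect_setequal(paste(sp$target_protein, sp$reference_protein),
                  paste(ep$target_protein, ep$reference_protein))
})

test_that("fixture files are byte-identical across runs with one seed", {
  mk <- function(dir) {
    uni <- generate_universe(n_reference_species = 2, n_target_proteins = 10,
                             inparalog_rate = 0.3, seed = 77)
    pl <- plant_reference_interactions(
      uni, data.frame(S = 2, E = 1, multiplicity = 1, count = 4), seed = 78)
    net <- build_network(predict_interactome(uni$clusters,
                                             pl$interactions)$predictions)
    ex <- generate_expression(net, 0.5, 12, seed = 79)
    write_fixture_dir(dir, uni, pl, expression = ex)
    dir
  }
  d1 <- mk(tempfile()); d2 <- mk(tempfile())
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("inparalog rate controls mean cluster size within binomial error", {
  uni <- generate_universe(n_reference_species = 1, n_target_proteins = 100,
                           inparalog_rate = 0.5, seed = 5)
  mc <- uni$manifest$member_counts
  extras <- (mc$n_target - 1) + (mc$n_reference - 1)  # Binomial(2, 0.5) each
  expect_lt(abs(mean(extras) - 1), 3 * sqrt(0.5 / length(extras)) * 2)
})

test_that("planted profiles yield the advertised CV ground truth", {
  uni <- generate_universe(n_reference_species = 4, n_target_proteins = 40,
                           seed = 15)
  pl <- plant_reference_interactions(
    uni, data.frame(S = c(4, 1), E = c(1, 1), multiplicity = c(1, 1),
                    count = c(10, 5)), seed = 16)
  m <- pl$manifest
  expect_equal(m$CV[m$S == 4], rep(16L, 10))
  expect_equal(m$bin[m$S == 1], rep("low", 5))

  expect_error(plant_reference_interactions(
    uni, data.frame(S = 9, E = 1, multiplicity = 1, count = 1)),
    "more species")
  expect_error(plant_reference_interactions(
    uni, data.frame(S = 1, E = 3, multiplicity = 1, count = 1)),
    "distinct methods")
})

test_that("expression generator plants the requested correlation and null", {
  net0 <- make_network(sprintf("TGT%06d_P01", 1:10),
                       sprintf("TGT%06d_P01", 11:20))
  ex0 <- generate_expression(net0, rho_edge = 0, n_samples = 30, seed = 9)
  ec0 <- edge_correlations(net0, ex0$expression)
  expect_lt(abs(mean(ec0$r)), 3 / sqrt(nrow(ec0) * 30))

  ex1 <- generate_expression(net0, rho_edge = 0.8, n_samples = 68, seed = 9)
  ec1 <- edge_correlations(net0, ex1$expression)
  expect_equal(nrow(ex1$manifest$planted_edges), 10)
  expect_lt(abs(mean(ec1$r) - 0.8), 0.1)

  expect_error(generate_expression(net0, rho_edge = 1, n_samples = 20,
                                   seed = 1), "rho")
  ex2 <- generate_expression(net0, rho_edge = 0.8, n_samples = 68, seed = 9)
  expect_identical(ex1$expression$values, ex2$expression$values)
})

test_that("end-to-end pipeline reproduces the planted prediction set exactly", {
  uni <- generate_universe(n_reference_species = 5, n_target_proteins = 40,
                           inparalog_rate = 0, bootstrap_fail_rate = 0,
                           seed = 25)
  prof <- data.frame(S = c(1, 2, 3, 5), E = c(1, 2, 1, 2),
                     multiplicity = c(1, 1, 2, 2), count = c(6, 6, 6, 6))
  pl <- plant_reference_interactions(uni, prof, seed = 26)
  res <- predict_interactome(uni$clusters, pl$interactions)
  p <- res$predictions$predictions
  m <- pl$manifest
  # with no inparalogs the predicted set IS the planted set
  expect_setequal(paste(p$protein_a, p$protein_b),
                  paste(m$protein_a, m$protein_b))
  j <- merge(m, p, by = c("protein_a", "protein_b"))
  expect_equal(j$cv, j$CV)
  expect_equal(j$n_species, j$S)
})
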