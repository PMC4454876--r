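test_that("canonical order puts the larger id first and is symmetric", {
  cp <- canonical_pair("GRMZM2G008327_P01", "GRMZM2G061287_P01")
  expect_equal(cp$protein_a, "GRMZM2G061287_P01")
  expect_equal(cp$protein_b, "GRMZM2G008327_P01")

  self <- canonical_pair("x", "x")
  expect_equal(self$protein_a, "x")
  expect_equal(self$protein_b, "x")

  expect_error(canonical_pair("", "y"), class = "interologr_validation_error")

  set.seed(42)
  a <- random_ids(500); b <- random_ids(500)
  fwd <- canonical_pair(a, b); rev <- canonical_pair(b, a)
  expect_equal(fwd, rev)
  # independent byte-order oracle via radix sort
  oracle_a <- mapply(function(x, y)
    sort(c(x, y), method = "radix", decreasing = TRUE)[1], a, b)
  expect_equal(fwd$protein_a, unname(oracle_a))
})

test_that("transfer emits the ortholog cross product and counts skips", {
  cl <- rbind(
    make_cluster("c1", tgt = list(c("m1", 1, 100), c("m2", 0.9, 50)),
                 ref = list(c("r1", 1, 100))),
    make_cluster("c2", tgt = list(c("m3", 1, 100)),
                 ref = list(c("r2", 1, 100))))
  om <- ortholog_map(expand_pairs(cl, "tgt"))
  refs <- make_refs(list("ref01", "r1", "r2"))
  pred <- transfer(refs, om, "many_to_many")
  expect_setequal(paste(pred$predictions$protein_a,
                        pred$predictions$protein_b),
                  c(paste(canonical_pair("m1", "m3")$protein_a,
                          canonical_pair("m1", "m3")$protein_b),
                    paste(canonical_pair("m2", "m3")$protein_a,
                          canonical_pair("m2", "m3")$protein_b)))
  expect_true(all(pred$predictions$n_support == 1))

  unmapped <- transfer(make_refs(list("ref01", "r1", "rX")), om,
                       "many_to_many")
  expect_equal(nrow(unmapped$predictions), 0)
  expect_equal(unmapped$skipped, 1L)
})

test_that("transfer equals a brute-force cross-product enumeration on fixtures", {
  uni <- generate_universe(n_reference_species = 3, n_target_proteins = 25,
                           inparalog_rate = 0.5, seed = 21)
  prof <- data.frame(S = c(1, 2, 3), E = c(1, 1, 2),
                     multiplicity = c(1, 2, 1), count = c(6, 6, 6))
  pl <- plant_reference_interactions(uni, prof, seed = 22)
  ep <- expand_pairs(uni$clusters, uni$target_species)
  pred <- transfer(pl$interactions, ortholog_map(ep), "many_to_many")

  # oracle: loop every reference row, enumerate T1 x T2 directly
  lookup <- function(sp, id)
    unique(ep$target_protein[ep$reference_species == sp &
                               ep$reference_protein == id])
  keys <- character(0)
  for (i in seq_len(nrow(pl$interactions))) {
    t1 <- lookup(pl$interactions$species[i], pl$interactions$id_a[i])
    t2 <- lookup(pl$interactions$species[i], pl$interactions$id_b[i])
    for (x in t1) for (y in t2) {
      cp <- canonical_pair(x, y)
      keys <- c(keys, paste(cp$protein_a, cp$protein_b))
    }
  }
  expect_setequal(paste(pred$predictions$protein_a,
                        pred$predictions$protein_b), unique(keys))
})

test_that("transfer is insensitive to row order and id_a/id_b swaps", {
  uni <- generate_universe(n_reference_species = 3, n_target_proteins = 20,
                           seed = 31)
  prof <- data.frame(S = 2, E = 2, multiplicity = 2, count = 8)
  pl <- plant_reference_interactions(uni, prof, seed = 32)
  om <- ortholog_map(expand_pairs(uni$clusters, uni$target_species))
  base <- transfer(pl$interactions, om, "many_to_many")$predictions

  refs2 <- pl$interactions[rev(seq_len(nrow(pl$interactions))), ]
  tmp <- refs2$id_a; refs2$id_a <- refs2$id_b; refs2$id_b <- tmp
  again <- transfer(refs2, om, "many_to_many")$predictions
  expect_equal(base, again)
})

test_that("support counts distinguish tuples, species and methods", {
  one <- data.frame(reference_species = "x", ref_a = "p1", ref_b = "p0",
                    method = "y2h", source_db = "A",
                    stringsAsFactors = FALSE)
  expect_equal(compute_support_counts(one), c(N = 1L, S = 1L, E = 1L))

  s <- data.frame(
    reference_species = c("x", "x", "y"),
    ref_a = c("p1", "p1", "p2"), ref_b = c("p0", "p0", "p0"),
    method = c("y2h", "y2h", "coip"),
    source_db = c("A", "B", "A"), stringsAsFactors = FALSE)
  expect_equal(compute_support_counts(s), c(N = 3L, S = 2L, E = 2L))

  four <- data.frame(reference_species = c("a", "b", "c", "d"),
                     ref_a = paste0("r", 1:4), ref_b = paste0("q", 1:4),
                     method = "y2h", source_db = "A",
                     stringsAsFactors = FALSE)
  expect_equal(compute_support_counts(four), c(N = 4L, S = 4L, E = 1L))
  expect_error(compute_support_counts(four[0, ]), "support")
})

test_that("confidence value is the N x S x E product with integer bins", {
  expect_equal(compute_cv(4, 4, 1), 16L)
  expect_equal(compute_cv(1, 1, 1), 1L)
  expect_equal(compute_cv(3, 2, 2), 12L)
  expect_error(compute_cv(0, 1, 1), class = "interologr_validation_error")

  expect_equal(assign_bin(1), "low")
  expect_equal(assign_bin(2), "medium")
  expect_equal(assign_bin(10), "medium")
  expect_equal(assign_bin(11), "high")
  expect_equal(assign_bin(12960), "high")
  expect_error(assign_bin(0), class = "interologr_validation_error")
})

test_that("scoring is a pure function of the support records", {
  uni <- generate_universe(n_reference_species = 4, n_target_proteins = 30,
                           seed = 41)
  prof <- data.frame(S = c(2, 4), E = c(2, 1), multiplicity = c(2, 1),
                     count = c(8, 8))
  pl <- plant_reference_interactions(uni, prof, seed = 42)
  pred <- transfer(pl$interactions,
                   ortholog_map(expand_pairs(uni$clusters,
                                             uni$target_species)),
                   "many_to_many")
  rescored <- interologr:::score_supports(pred$supports)
  expect_equal(rescored, pred$predictions)
  # CV >= S^2 because N >= S and E >= 1
  expect_true(all(pred$predictions$cv >=
                    pred$predictions$n_species^2))
})

test_that("merge partitions interactions and proteins consistently", {
  cl <- rbind(
    make_cluster("c1", list(c("m1", 1, 100)), list(c("r1", 1, 100))),
    make_cluster("c2", list(c("m2", 1, 100)), list(c("r2", 1, 100))),
    make_cluster("c3", list(c("m3", 1, 90), c("m3b", 1, 100)),
                 list(c("r3", 1, 100))))
  refs <- make_refs(list("ref01", "r1", "r2"),  # transfers in both schemes
                    list("ref01", "r1", "r3"))  # c3 seed = m3b; mtm adds m3
  res <- predict_interactome(cl, refs, "tgt")
  p <- res$predictions$predictions
  expect_true(all(p$in_one_to_one | p$in_many_to_many))
  si <- res$summary$interactions
  expect_equal(si[["one_to_one_unique"]] + si[["many_to_many_unique"]] +
                 si[["overlap"]], si[["combined_unique"]])
  sp <- res$summary$proteins
  expect_equal(sp[["one_to_one_unique"]] + sp[["many_to_many_unique"]] +
                 sp[["overlap"]], sp[["combined_unique"]])

  # disjoint and overlapping toy partitions via the set oracle
  oto_keys <- unique(paste(p$protein_a, p$protein_b)[p$in_one_to_one])
  mtm_keys <- unique(paste(p$protein_a, p$protein_b)[p$in_many_to_many])
  expect_equal(si[["overlap"]], length(intersect(oto_keys, mtm_keys)))
  expect_equal(si[["combined_unique"]], length(union(oto_keys, mtm_keys)))
})

test_that("per-species fold changes match direct ratios", {
  expect_equal(round(species_fold_change(4289, 7331), 9), 1.709256237)
  expect_lt(abs(species_fold_change(60, 923) - 15.38333333), 5e-9)
  expect_equal(species_fold_change(7, 7), 1)
  expect_true(is.na(species_fold_change(0, 5)))

  uni <- generate_universe(n_reference_species = 3, n_target_proteins = 20,
                           seed = 51)
  pl <- plant_reference_interactions(
    uni, data.frame(S = 2, E = 1, multiplicity = 1, count = 6), seed = 52)
  res <- predict_interactome(uni$clusters, pl$interactions)
  tab <- per_species_summary(res$predictions)
  expect_equal(tab$total,
               tab$one_to_one_interologs + tab$many_to_many_interologs)
  expect_equal(tab$fold_change,
               ifelse(tab$one_to_one_interologs > 0,
                      tab$many_to_many_interologs /
                        tab$one_to_one_interologs, NA_real_))
})

test_that("conservation filtering retains S >= threshold and is monotone", {
  uni <- generate_universe(n_reference_species = 5, n_target_proteins = 40,
                           seed = 61)
  prof <- data.frame(S = c(1, 3, 4, 5), E = 1, multiplicity = 1,
                     count = c(5, 5, 5, 5))
  pl <- plant_reference_interactions(uni, prof, seed = 62)
  pred <- transfer(pl$interactions,
                   ortholog_map(seed_pairs(uni$clusters,
                                           uni$target_species)),
                   "one_to_one")
  f4 <- filter_by_conservation(pred, 4)
  f5 <- filter_by_conservation(pred, 5)
  expect_true(all(f4$predictions$n_species >= 4))
  k <- function(x) paste(x$predictions$protein_a, x$predictions$protein_b)
  expect_true(all(k(f5) %in% k(f4)))
  m <- pl$manifest
  expect_equal(sum(f4$predictions$n_species >= 4), nrow(f4$predictions))
  expect_equal(nrow(f4$predictions), sum(m$S >= 4))
  expect_equal(nrow(f5$predictions), sum(m$S >= 5))
})

test_that("prediction tables round-trip through the TSV writer", {
  uni <- generate_universe(n_reference_species = 3, n_target_proteins = 15,
                           seed = 71)
  pl <- plant_reference_interactions(
    uni, data.frame(S = 2, E = 2, multiplicity = 1, count = 5), seed = 72)
  res <- predict_interactome(uni$clusters, pl$interactions)
  path <- file.path(tempfile(), "pred.tsv")
  write_predictions(res$predictions, path)
  back <- read_predictions(path)
  p <- res$predictions$predictions
  expect_equal(back$protein_a, p$protein_a)
  expect_equal(back$cv, p$cv)
  expect_equal(back$in_one_to_one, p$in_one_to_one)
})
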