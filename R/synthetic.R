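# Synthetic fixture generation: internally consistent toy proteomes,
# ortholog clusters, reference interaction sets, GO annotations and
# expression matrices, together with a ground-truth manifest from which
# every expected pipeline output can be recomputed without running the
# pipeline. All generators are deterministic for a fixed seed.

TARGET_SPECIES <- "tgt"

ref_species_tags <- function(n) {
  if (n < 1 || n > 13)
    stop_validation("n_reference_species must be in 1..13")
  sprintf("ref%02d", seq_len(n))
}

target_protein_id <- function(i, model = 1)
  sprintf("TGT%06d_P%02d", i, model)

ref_protein_id <- function(species, i, model = 1)
  sprintf("%s_%06d_R%02d", toupper(species), i, model)

#' Generate a synthetic ortholog-cluster universe
#'
#' Builds a toy target proteome and, for each of `n_reference_species`
#' reference species, one ortholog cluster per target protein. Every
#' cluster has one seed member per species (inparalog score 1.0,
#' bootstrap 100) plus extra inparalogs at `inparalog_rate` per side
#' (lower scores, sub-100 bootstrap); a `bootstrap_fail_rate` fraction of
#' clusters have their bootstrap knocked below 100 on the target side so
#' they contribute to many-to-many but not one-to-one mapping.
#'
#' @param n_reference_species Number of reference species (1-13).
#' @param n_target_proteins Number of target proteins (= clusters per
#'   reference species).
#' @param inparalog_rate Per-side probability of one extra inparalog.
#' @param bootstrap_fail_rate Fraction of clusters failing the
#'   bootstrap-100 seed criterion.
#' @param seed Integer RNG seed.
#' @return A list: `clusters` (an `ortholog_clusters` member table over
#'   all species), `target_species`, `reference_species`, and `manifest`
#'   (planted ground truth: per-cluster member counts, failed clusters,
#'   expected seed/expanded pair counts).
#' @export
generate_universe <- function(n_reference_species = 4,
                              n_target_proteins = 50,
                              inparalog_rate = 0.3,
                              bootstrap_fail_rate = 0.1,
                              seed = 1) {
  if (inparalog_rate < 0 || inparalog_rate > 1 ||
      bootstrap_fail_rate < 0 || bootstrap_fail_rate > 1)
    stop_validation("rates must be in [0,1]")
  species <- ref_species_tags(n_reference_species)
  with_seed(seed, {
    rows <- list()
    failed <- data.frame(cluster_id = character(0), species = character(0),
                         stringsAsFactors = FALSE)
    per_cluster <- list()
    for (sp in species) {
      for (i in seq_len(n_target_proteins)) {
        cid <- sprintf("C%06d_%s", i, sp)
        fail <- stats::runif(1) < bootstrap_fail_rate
        tgt_boot <- if (fail) 90L else 100L
        tgt <- data.frame(cluster_id = cid, species_tag = TARGET_SPECIES,
                          protein_id = target_protein_id(i),
                          inparalog_score = 1,
                          bootstrap_percent = tgt_boot,
                          stringsAsFactors = FALSE)
        if (stats::runif(1) < inparalog_rate)
          tgt <- rbind(tgt, data.frame(
            cluster_id = cid, species_tag = TARGET_SPECIES,
            protein_id = target_protein_id(i, 2),
            inparalog_score = round(stats::runif(1, 0.5, 0.99), 3),
            bootstrap_percent = sample(10:95, 1), stringsAsFactors = FALSE))
        ref <- data.frame(cluster_id = cid, species_tag = sp,
                          protein_id = ref_protein_id(sp, i),
                          inparalog_score = 1, bootstrap_percent = 100L,
                          stringsAsFactors = FALSE)
        if (stats::runif(1) < inparalog_rate)
          ref <- rbind(ref, data.frame(
            cluster_id = cid, species_tag = sp,
            protein_id = ref_protein_id(sp, i, 2),
            inparalog_score = round(stats::runif(1, 0.5, 0.99), 3),
            bootstrap_percent = sample(10:95, 1), stringsAsFactors = FALSE))
        rows[[cid]] <- rbind(tgt, ref)
        if (fail) failed <- rbind(failed, data.frame(
          cluster_id = cid, species = sp, stringsAsFactors = FALSE))
        per_cluster[[cid]] <- c(n_target = nrow(tgt), n_reference = nrow(ref))
      }
    }
    members <- do.call(rbind, rows)
    rownames(members) <- NULL
    pc <- do.call(rbind, per_cluster)
    manifest <- list(
      seed = seed,
      n_reference_species = n_reference_species,
      n_target_proteins = n_target_proteins,
      inparalog_rate = inparalog_rate,
      bootstrap_fail_rate = bootstrap_fail_rate,
      n_clusters = length(rows),
      member_counts = data.frame(cluster_id = rownames(pc),
                                 n_target = pc[, "n_target"],
                                 n_reference = pc[, "n_reference"],
                                 row.names = NULL, stringsAsFactors = FALSE),
      failed_clusters = failed,
      expected_seed_pairs = length(rows) - nrow(failed),
      expected_expanded_pairs = sum(pc[, "n_target"] * pc[, "n_reference"]))
    list(clusters = validate_clusters(members),
         target_species = TARGET_SPECIES,
         reference_species = species,
         manifest = manifest)
  })
}

clean_targets <- function(universe) {
  failed_idx <- unique(as.integer(sub("^C([0-9]+)_.*$", "\\1",
                                      universe$manifest$failed_clusters$cluster_id)))
  setdiff(seq_len(universe$manifest$n_target_proteins), failed_idx)
}

#' Plant reference interactions with known confidence ground truth
#'
#' For each profile row, plants `count` target protein pairs with support
#' in exactly `S` reference species, `E` distinct method labels and
#' `multiplicity` database records per species, so the ground-truth
#' confidence value of each planted pair is
#' `CV = (S x multiplicity) x S x E`. Endpoints are drawn from clusters
#' that pass the bootstrap criterion everywhere, so the one-to-one and
#' many-to-many transfers both recover the planted evidence exactly.
#' Raw id order of roughly half the rows is swapped to exercise
#' canonicalization.
#'
#' @param universe A universe from [generate_universe()].
#' @param profile Data frame with columns `S`, `E`, `multiplicity`,
#'   `count`.
#' @param seed Integer RNG seed.
#' @return A list: `interactions` (a `reference_interactions` data
#'   frame) and `manifest` (data frame of planted pairs with their
#'   N, S, E, CV, bin and supporting species).
#' @export
plant_reference_interactions <- function(universe, profile, seed = 1) {
  stopifnot(all(c("S", "E", "multiplicity", "count") %in% names(profile)))
  n_sp <- length(universe$reference_species)
  if (any(profile$S > n_sp))
    stop_validation("profile requests more species than the universe has")
  if (any(profile$E > profile$S * profile$multiplicity))
    stop_validation("cannot realize E distinct methods with fewer records")
  ok_targets <- clean_targets(universe)
  n_pairs_needed <- sum(profile$count)
  if (choose(length(ok_targets), 2) < n_pairs_needed)
    stop_validation("not enough clean target proteins for the profile")
  with_seed(seed, {
    all_pairs <- utils::combn(ok_targets, 2)
    sel <- sample(ncol(all_pairs), n_pairs_needed)
    pair_idx <- all_pairs[, sel, drop = FALSE]
    rows <- list()
    planted <- list()
    p <- 0L
    for (row in seq_len(nrow(profile))) {
      S <- profile$S[row]; E <- profile$E[row]
      mult <- profile$multiplicity[row]
      for (j in seq_len(profile$count[row])) {
        p <- p + 1L
        t1 <- pair_idx[1, p]; t2 <- pair_idx[2, p]
        sps <- sample(universe$reference_species, S)
        methods <- sprintf("method%02d", seq_len(E))
        k <- 0L
        for (sp in sps) {
          r1 <- ref_protein_id(sp, t1); r2 <- ref_protein_id(sp, t2)
          for (m in seq_len(mult)) {
            k <- k + 1L
            swap <- stats::runif(1) < 0.5
            rows[[length(rows) + 1L]] <- data.frame(
              species = sp,
              id_a = if (swap) r2 else r1,
              id_b = if (swap) r1 else r2,
              method = methods[(k - 1L) %% E + 1L],
              source_db = sprintf("DB%02d", m),
              publication = sprintf("PUB%05d", p),
              stringsAsFactors = FALSE)
          }
        }
        cp <- canonical_pair(target_protein_id(t1), target_protein_id(t2))
        cv <- (S * mult) * S * E
        planted[[p]] <- data.frame(
          protein_a = cp$protein_a, protein_b = cp$protein_b,
          N = S * mult, S = S, E = E, CV = cv, bin = assign_bin(cv),
          species = paste(sort(sps), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    interactions <- do.call(rbind, rows)
    interactions <- interactions[sample(nrow(interactions)), , drop = FALSE]
    rownames(interactions) <- NULL
    class(interactions) <- c("reference_interactions", "data.frame")
    manifest <- do.call(rbind, planted)
    rownames(manifest) <- NULL
    list(interactions = interactions, manifest = manifest)
  })
}

#' Generate an expression matrix with planted edge co-expression
#'
#' Simulates M-value profiles over `n_samples` contrasts. Each network
#' edge whose two genes are both still unassigned receives a shared
#' latent signal giving an expected pairwise Pearson correlation of
#' `rho_edge`; all remaining genes are independent standard normal.
#' Edges planted cleanly (both genes fresh at assignment time) are listed
#' in the manifest — on a matching (disjoint edges) every edge is clean.
#'
#' @param network A `ppi_network`.
#' @param rho_edge Target correlation in (-1, 1).
#' @param n_samples Number of contrast columns (>= 10; the default 68
#'   mirrors a typical stress-microarray compendium).
#' @param seed Integer RNG seed.
#' @param mapping Optional protein -> gene mapping (default suffix
#'   stripping).
#' @return A list: `expression` (an `expression_matrix` of M-values) and
#'   `manifest` (`rho`, `n_samples`, `planted_edges` data frame).
#' @export
generate_expression <- function(network, rho_edge = 0.8, n_samples = 68,
                                seed = 1, mapping = NULL) {
  if (abs(rho_edge) >= 1) stop_validation("rho_edge must be in (-1, 1)")
  if (n_samples < 10) stop_validation("need n_samples >= 10")
  genes <- unique(unname(map_genes(network$nodes, mapping)))
  with_seed(seed, {
    vals <- matrix(NA_real_, nrow = length(genes), ncol = n_samples,
                   dimnames = list(genes, sprintf("contrast%02d",
                                                  seq_len(n_samples))))
    assigned <- character(0)
    planted <- list()
    e <- network$edges[network$edges$protein_a != network$edges$protein_b, ,
                       drop = FALSE]
    ga <- map_genes(e$protein_a, mapping); gb <- map_genes(e$protein_b, mapping)
    a <- sqrt(abs(rho_edge)); b <- sqrt(1 - abs(rho_edge))
    sgn <- sign(rho_edge)
    for (i in seq_len(nrow(e))) {
      if (ga[i] %in% assigned || gb[i] %in% assigned || ga[i] == gb[i]) next
      z <- stats::rnorm(n_samples)
      vals[ga[i], ] <- a * z + b * stats::rnorm(n_samples)
      vals[gb[i], ] <- sgn * a * z + b * stats::rnorm(n_samples)
      assigned <- c(assigned, ga[i], gb[i])
      planted[[length(planted) + 1L]] <- data.frame(
        protein_a = e$protein_a[i], protein_b = e$protein_b[i],
        gene_a = unname(ga[i]), gene_b = unname(gb[i]),
        stringsAsFactors = FALSE)
    }
    rest <- setdiff(genes, assigned)
    if (length(rest) > 0)
      vals[rest, ] <- matrix(stats::rnorm(length(rest) * n_samples),
                             nrow = length(rest))
    planted_df <- if (length(planted) == 0)
      data.frame(protein_a = character(0), protein_b = character(0),
                 gene_a = character(0), gene_b = character(0),
                 stringsAsFactors = FALSE)
    else do.call(rbind, planted)
    list(expression = structure(list(values = vals, mode = "m_values"),
                                class = "expression_matrix"),
         manifest = list(rho = rho_edge, n_samples = n_samples, seed = seed,
                         planted_edges = planted_df))
  })
}

#' Generate GO annotations with one planted enriched term
#'
#' Builds a background universe, a planted term covering
#' `term_bg_count` background proteins, and `n_null_terms` null terms of
#' similar coverage; the foreground is drawn so the planted term is
#' represented about `planted_fold` times its chance expectation while
#' null-term membership is left to chance.
#'
#' @param bg_size,fg_size Background and foreground sizes.
#' @param n_null_terms Number of unenriched terms.
#' @param term_bg_count Background coverage of every term.
#' @param planted_fold Target enrichment of the planted term.
#' @param seed Integer RNG seed.
#' @return A list: `foreground`, `background`, `annotations`
#'   (a `go_annotations` data frame), `planted_term`.
#' @export
plant_enriched_annotations <- function(bg_size = 2000, fg_size = 200,
                                       n_null_terms = 50,
                                       term_bg_count = 100,
                                       planted_fold = 5, seed = 1) {
  expected <- term_bg_count * fg_size / bg_size
  target_obs <- round(planted_fold * expected)
  if (target_obs > min(fg_size, term_bg_count))
    stop_validation("planted fold not realizable at these sizes")
  with_seed(seed, {
    background <- sprintf("P%06d", seq_len(bg_size))
    planted_term <- "GO:PLANTED"
    members <- sample(background, term_bg_count)
    foreground <- c(sample(members, target_obs),
                    sample(setdiff(background, members),
                           fg_size - target_obs))
    ann <- list(data.frame(protein_id = members, go_term = planted_term,
                           aspect = "P", stringsAsFactors = FALSE))
    for (t in seq_len(n_null_terms)) {
      ann[[t + 1L]] <- data.frame(
        protein_id = sample(background, term_bg_count),
        go_term = sprintf("GO:NULL%03d", t), aspect = "P",
        stringsAsFactors = FALSE)
    }
    annotations <- do.call(rbind, ann)
    class(annotations) <- c("go_annotations", "data.frame")
    list(foreground = foreground, background = background,
         annotations = annotations, planted_term = planted_term)
  })
}

#' Write a complete fixture directory
#'
#' Materializes a synthetic universe and its companion inputs as the
#' plain-text files the readers consume: `clusters/<species>.tsv`,
#' `interactions/<species>.tsv`, `go.tsv`, `expr.tsv` and a
#' machine-readable `manifest.json`.
#'
#' @param dir Output directory (created).
#' @param universe From [generate_universe()].
#' @param interactions Optional result of [plant_reference_interactions()].
#' @param annotations Optional `go_annotations` data frame.
#' @param expression Optional result of [generate_expression()].
#' @return Invisibly, `dir`.
#' @export
write_fixture_dir <- function(dir, universe, interactions = NULL,
                              annotations = NULL, expression = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- universe$clusters
  manifest <- list(universe = universe$manifest)
  for (sp in universe$reference_species) {
    keep <- cl$cluster_id %in%
      cl$cluster_id[cl$species_tag == sp]
    write_tsv_atomic(as.data.frame(cl[keep, , drop = FALSE]),
                     file.path(dir, "clusters", paste0(sp, ".tsv")))
  }
  if (!is.null(interactions)) {
    ia <- interactions$interactions
    for (sp in unique(ia$species))
      write_tsv_atomic(as.data.frame(ia[ia$species == sp, , drop = FALSE]),
                       file.path(dir, "interactions", paste0(sp, ".tsv")))
    manifest$planted_interactions <- interactions$manifest
  }
  if (!is.null(annotations))
    write_tsv_atomic(as.data.frame(annotations), file.path(dir, "go.tsv"))
  if (!is.null(expression)) {
    em <- expression$expression
    df <- data.frame(gene_id = rownames(em$values),
                     em$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv_atomic(df, file.path(dir, "expr.tsv"))
    manifest$expression <- expression$manifest[c("rho", "n_samples", "seed")]
  }
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           dataframe = "columns")
  writeLines(json, file.path(dir, "manifest.json"))
  invisible(dir)
}
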