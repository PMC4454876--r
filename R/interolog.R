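# Interolog transfer and confidence scoring.
#
# A reference interaction (r1, r2) observed in species s maps onto the
# target species wherever both endpoints have orthologs: every pair in
# T(r1) x T(r2) becomes a predicted interaction, carrying one support
# record per (reference row, emitted pair). Predictions are canonicalized
# (larger id first) and deduplicated; each then gets a confidence value
#
#   CV = N x S x E
#
# where N counts distinct (reference species, reference pair, source
# database) support tuples, S counts distinct supporting reference
# species, and E counts distinct experimental method labels. CV = 1 is
# low confidence, 2-10 medium, > 10 high.

empty_supports <- function() {
  data.frame(protein_a = character(0), protein_b = character(0),
             reference_species = character(0), ref_a = character(0),
             ref_b = character(0), method = character(0),
             source_db = character(0), scheme = character(0),
             stringsAsFactors = FALSE)
}

#' Transfer reference interactions onto the target species
#'
#' Maps each experimentally observed reference interaction through an
#' ortholog map and emits every cross combination of the two endpoints'
#' target orthologs as a predicted interaction. Reference pairs are
#' canonicalized per species before support counting (so a database row
#' and its mirror are one reference pair); predictions are canonicalized
#' and merged on the target pair, accumulating support records. Reference
#' rows with an unmapped endpoint are skipped and counted.
#'
#' @param refs A `reference_interactions` data frame.
#' @param omap An [ortholog_map()] built under the requested scheme.
#' @param scheme Label stored on the support records: `"one_to_one"` or
#'   `"many_to_many"`.
#' @return An `interolog_predictions` object: list with the scored
#'   `predictions` data frame, the raw `supports` data frame, and
#'   `skipped` (count of untransferable reference rows).
#' @export
transfer <- function(refs, omap, scheme = c("one_to_one", "many_to_many")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(refs), inherits(omap, "ortholog_map"))
  n <- nrow(refs)
  rows <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    t1 <- omap_lookup(omap, refs$species[i], refs$id_a[i])
    t2 <- omap_lookup(omap, refs$species[i], refs$id_b[i])
    if (is.null(t1) || is.null(t2)) {
      skipped <- skipped + 1L
      next
    }
    grid <- expand.grid(a = t1, b = t2, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    cp <- canonical_pair(grid$a, grid$b)
    cp <- unique(cp)  # symmetric duplicates within one cross product
    rp <- canonical_pair(refs$id_a[i], refs$id_b[i])
    rows[[i]] <- data.frame(
      protein_a = cp$protein_a, protein_b = cp$protein_b,
      reference_species = refs$species[i],
      ref_a = rp$protein_a, ref_b = rp$protein_b,
      method = refs$method[i], source_db = refs$source_db[i],
      scheme = scheme, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  supports <- if (length(rows) == 0) empty_supports() else do.call(rbind, rows)
  rownames(supports) <- NULL
  new_predictions(supports, skipped = skipped)
}

new_predictions <- function(supports, skipped = 0L) {
  structure(list(predictions = score_supports(supports),
                 supports = supports, skipped = skipped),
            class = "interolog_predictions")
}

# Score every canonical pair present in a support table.
score_supports <- function(supports) {
  if (nrow(supports) == 0) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      n_support = integer(0), n_species = integer(0),
                      n_methods = integer(0), cv = integer(0),
                      bin = character(0), supporting_species = character(0),
                      methods = character(0), stringsAsFactors = FALSE))
  }
  key <- pair_key(supports$protein_a, supports$protein_b)
  idx <- split(seq_len(nrow(supports)), key)
  out <- lapply(idx, function(i) {
    s <- supports[i, , drop = FALSE]
    cnt <- compute_support_counts(s)
    data.frame(protein_a = s$protein_a[1], protein_b = s$protein_b[1],
               n_support = cnt[["N"]], n_species = cnt[["S"]],
               n_methods = cnt[["E"]],
               cv = compute_cv(cnt[["N"]], cnt[["S"]], cnt[["E"]]),
               bin = assign_bin(compute_cv(cnt[["N"]], cnt[["S"]], cnt[["E"]])),
               supporting_species = paste(sort(unique(s$reference_species)),
                                          collapse = ";"),
               methods = paste(sort(unique(s$method)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$cv, out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count support evidence for one predicted interaction
#'
#' Computes the three evidence counts behind the confidence value from a
#' table of support records: `N`, the number of distinct (reference
#' species, canonical reference pair, source database) tuples; `S`, the
#' number of distinct reference species; `E`, the number of distinct
#' experimental method labels. By construction `S <= N`.
#'
#' @param supports A non-empty support-record data frame for a single
#'   predicted pair (columns `reference_species`, `ref_a`, `ref_b`,
#'   `method`, `source_db`).
#' @return Named integer vector `c(N =, S =, E =)`.
#' @export
compute_support_counts <- function(supports) {
  if (!is.data.frame(supports) || nrow(supports) == 0)
    stop_validation("a predicted interaction needs at least one support record")
  n_tuples <- length(unique(paste(supports$reference_species, supports$ref_a,
                                  supports$ref_b, supports$source_db,
                                  sep = "\r")))
  c(N = n_tuples,
    S = length(unique(supports$reference_species)),
    E = length(unique(supports$method)))
}

#' Confidence value of a predicted interaction
#'
#' `CV = N x S x E`: the product of the support-record count, the
#' supporting-species count and the distinct-experiment-type count. The
#' minimum CV of an interaction supported in exactly four reference
#' species (one record each, one method) is therefore 4 x 4 x 1 = 16.
#'
#' @param N,S,E Positive integers (vectorized).
#' @return Integer CV.
#' @examples
#' compute_cv(4, 4, 1)  # 16
#' @export
compute_cv <- function(N, S, E) {
  if (any(N < 1 | S < 1 | E < 1) || anyNA(c(N, S, E)))
    stop_validation("N, S and E must all be >= 1")
  as.integer(N) * as.integer(S) * as.integer(E)
}

#' Confidence bin of a CV
#'
#' CV = 1 is low confidence, CV in 2-10 medium, CV > 10 high.
#'
#' @param cv Positive integer vector of confidence values.
#' @return Character vector in `{"low", "medium", "high"}`.
#' @export
assign_bin <- function(cv) {
  if (any(cv < 1) || anyNA(cv)) stop_validation("CV must be >= 1")
  ifelse(cv == 1, "low", ifelse(cv <= 10, "medium", "high"))
}

prediction_keys <- function(pred) {
  pair_key(pred$predictions$protein_a, pred$predictions$protein_b)
}

#' Merge the one-to-one and many-to-many prediction sets
#'
#' Unions the two scheme-specific prediction sets on canonical pairs,
#' re-scores (N, S, E, CV) on the merged supports, flags each combined
#' interaction by scheme membership, and partitions both interactions and
#' proteins into scheme-only and overlap classes.
#'
#' @param oto,mtm `interolog_predictions` from [transfer()] under the
#'   one-to-one and many-to-many ortholog maps.
#' @return A list: `predictions` (combined `interolog_predictions` whose
#'   table carries `in_one_to_one` / `in_many_to_many` flags) and
#'   `summary` (partition counts for interactions and proteins).
#' @export
merge_and_partition <- function(oto, mtm) {
  stopifnot(inherits(oto, "interolog_predictions"),
            inherits(mtm, "interolog_predictions"))
  supports <- rbind(oto$supports, mtm$supports)
  combined <- new_predictions(supports,
                              skipped = oto$skipped + mtm$skipped)
  keys <- prediction_keys(combined)
  k_oto <- unique(prediction_keys(oto))
  k_mtm <- unique(prediction_keys(mtm))
  combined$predictions$in_one_to_one <- keys %in% k_oto
  combined$predictions$in_many_to_many <- keys %in% k_mtm
  part_int <- partition_counts(k_oto, k_mtm)
  p_oto <- pair_proteins(oto$predictions)
  p_mtm <- pair_proteins(mtm$predictions)
  part_prot <- partition_counts(p_oto, p_mtm)
  list(predictions = combined,
       summary = list(interactions = part_int, proteins = part_prot))
}

pair_proteins <- function(pred_df) unique(c(pred_df$protein_a, pred_df$protein_b))

partition_counts <- function(a, b) {
  both <- length(intersect(a, b))
  c(one_to_one_total = length(a),
    many_to_many_total = length(b),
    one_to_one_unique = length(a) - both,
    many_to_many_unique = length(b) - both,
    overlap = both,
    combined_unique = length(union(a, b)))
}

#' Per-reference-species interolog summary
#'
#' For each reference species, counts the distinct predicted interactions
#' it supports under each scheme, and reports the many-to-many/one-to-one
#' fold change (`NA` when the one-to-one count is zero) and the scheme
#' total.
#'
#' @param combined The combined `interolog_predictions` from
#'   [merge_and_partition()] (its supports carry species and scheme).
#' @return A data frame, one row per reference species.
#' @export
per_species_summary <- function(combined) {
  s <- if (inherits(combined, "interolog_predictions")) combined$supports
       else combined
  species <- sort(unique(s$reference_species))
  rows <- lapply(species, function(sp) {
    ss <- s[s$reference_species == sp, , drop = FALSE]
    cnt <- function(sch) length(unique(pair_key(ss$protein_a, ss$protein_b)[
      ss$scheme == sch]))
    oto <- cnt("one_to_one"); mtm <- cnt("many_to_many")
    data.frame(species = sp, one_to_one_interologs = oto,
               many_to_many_interologs = mtm,
               fold_change = species_fold_change(oto, mtm),
               total = oto + mtm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Many-to-many over one-to-one fold change
#'
#' The ratio of many-to-many to one-to-one interolog counts for one
#' reference species, undefined (`NA`) when the one-to-one count is zero.
#' Summaries print it with nine decimal places.
#'
#' @param oto,mtm Non-negative interolog counts.
#' @return The ratio `mtm / oto` at full precision, or `NA`.
#' @examples
#' species_fold_change(4289, 7331)  # 1.709256237
#' @export
species_fold_change <- function(oto, mtm) {
  ifelse(oto > 0, mtm / oto, NA_real_)
}

#' Keep only predictions conserved across enough species
#'
#' Retains predictions supported in at least `min_species` reference
#' species (`S >= min_species`); the result is monotone in the threshold.
#'
#' @param pred An `interolog_predictions` object.
#' @param min_species Minimum supporting-species count.
#' @return A filtered `interolog_predictions` object.
#' @export
filter_by_conservation <- function(pred, min_species) {
  stopifnot(inherits(pred, "interolog_predictions"), min_species >= 0)
  keep <- pred$predictions$n_species >= min_species
  kept_keys <- prediction_keys(pred)[keep]
  s <- pred$supports
  s <- s[pair_key(s$protein_a, s$protein_b) %in% kept_keys, , drop = FALSE]
  out <- pred
  out$predictions <- pred$predictions[keep, , drop = FALSE]
  rownames(out$predictions) <- NULL
  out$supports <- s
  out
}

#' Write a scored prediction table
#'
#' Writes the tab-delimited prediction table (protein pair, N, S, E, CV,
#' bin, scheme flags, supporting species and method lists).
#'
#' @param pred An `interolog_predictions` object.
#' @param path Output TSV path.
#' @param comments Optional comment lines written with a `#` prefix.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(pred, path, comments = character(0)) {
  df <- pred$predictions
  if (is.null(df$in_one_to_one)) df$in_one_to_one <- NA
  if (is.null(df$in_many_to_many)) df$in_many_to_many <- NA
  out <- data.frame(protein_a = df$protein_a, protein_b = df$protein_b,
                    N = df$n_support, S = df$n_species, E = df$n_methods,
                    CV = df$cv, bin = df$bin,
                    in_one_to_one = df$in_one_to_one,
                    in_many_to_many = df$in_many_to_many,
                    supporting_species = df$supporting_species,
                    methods = df$methods, stringsAsFactors = FALSE)
  write_tsv_atomic(out, path, comments)
}

#' @export
print.interolog_predictions <- function(x, ...) {
  cat("interolog_predictions:", nrow(x$predictions), "predicted interactions,",
      nrow(x$supports), "support records,", x$skipped,
      "reference rows skipped\n")
  invisible(x)
}
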