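# GO term enrichment/depletion of a foreground protein set against a
# background, by one-sided hypergeometric tests with Benjamini-Hochberg
# correction. Annotations are used flat (no propagation to ancestor
# terms); a propagation hook accepting a child->parent table is provided
# but off by default.

annotation_pairs <- function(annotations) {
  stopifnot(is.data.frame(annotations),
            all(c("protein_id", "go_term") %in% names(annotations)))
  if (!("aspect" %in% names(annotations))) annotations$aspect <- NA_character_
  unique(annotations[, c("protein_id", "go_term", "aspect")])
}

#' Propagate annotations up a term parentage table
#'
#' Optionally extends each protein's term set with all ancestors reachable
#' through a flat child -> parent table, so enrichment can be run on an
#' ancestor-closed annotation. Off by default in [enrich()].
#'
#' @param annotations A `go_annotations` data frame.
#' @param parents Data frame with columns `child`, `parent`.
#' @return The annotation data frame closed under parentage.
#' @export
propagate_annotations <- function(annotations, parents) {
  ann <- annotation_pairs(annotations)
  pmap <- split(parents$parent, parents$child)
  repeat {
    up <- ann
    anc <- pmap[up$go_term]
    has <- !vapply(anc, is.null, logical(1))
    if (!any(has)) break
    add <- do.call(rbind, lapply(which(has), function(i)
      data.frame(protein_id = up$protein_id[i], go_term = anc[[i]],
                 aspect = up$aspect[i], stringsAsFactors = FALSE)))
    merged <- unique(rbind(ann, add))
    if (nrow(merged) == nrow(ann)) break
    ann <- merged
  }
  rownames(ann) <- NULL
  ann
}

#' Term census of a protein set
#'
#' Counts the distinct proteins annotated to each term within a protein
#' set; proteins carrying no annotation at all are tallied in an
#' `unannotated` bucket.
#'
#' @param proteins Character vector of protein ids.
#' @param annotations A `go_annotations` data frame.
#' @return A list: `counts` (named integer vector term -> protein count)
#'   and `unannotated` (count of proteins with no term).
#' @export
term_census <- function(proteins, annotations) {
  proteins <- unique(proteins)
  ann <- annotation_pairs(annotations)
  ann <- ann[ann$protein_id %in% proteins, , drop = FALSE]
  counts <- if (nrow(ann) == 0) integer(0) else {
    tab <- tapply(ann$protein_id, ann$go_term,
                  function(p) length(unique(p)))
    stats::setNames(as.integer(tab), names(tab))
  }
  list(counts = counts,
       unannotated = length(setdiff(proteins, ann$protein_id)))
}

#' One-sided hypergeometric tail probability
#'
#' The probability, under uniform sampling of `fg_size` proteins from a
#' background of `bg_size` containing `term_bg_count` term members, of
#' observing at least (`enriched`) or at most (`depleted`) `observed`
#' term members — inclusive of the observed count.
#'
#' @param observed Observed term count in the foreground.
#' @param fg_size Foreground size.
#' @param term_bg_count Term count in the background.
#' @param bg_size Background size.
#' @param direction `"enriched"` (upper tail) or `"depleted"` (lower).
#' @return The one-sided p-value.
#' @export
hypergeometric_p <- function(observed, fg_size, term_bg_count, bg_size,
                             direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  if (fg_size > bg_size || term_bg_count > bg_size ||
      observed > min(fg_size, term_bg_count) || observed < 0)
    stop_validation("inconsistent counts for hypergeometric test")
  if (direction == "enriched")
    stats::phyper(observed - 1, term_bg_count, bg_size - term_bg_count,
                  fg_size, lower.tail = FALSE)
  else
    stats::phyper(observed, term_bg_count, bg_size - term_bg_count,
                  fg_size, lower.tail = TRUE)
}

#' Fold change of a term's representation
#'
#' Enrichment fold is observed/expected; depletion fold is
#' expected/observed (so both are >= 1 in their reported direction).
#' Summaries print two decimals: 181 observed vs 299.3 expected is a
#' 1.65-fold depletion.
#'
#' @param observed Observed foreground count.
#' @param expected Expected foreground count.
#' @param direction `"enriched"` or `"depleted"`.
#' @return The fold change, or `NA` when the denominator is zero.
#' @export
fold_change <- function(observed, expected, direction = c("enriched",
                                                          "depleted")) {
  direction <- match.arg(direction)
  den <- if (direction == "enriched") expected else observed
  if (!(den > 0)) return(NA_real_)
  if (direction == "enriched") observed / expected else expected / observed
}

#' GO term enrichment and depletion
#'
#' Tests every term annotated in the background for over- or
#' under-representation in the foreground (e.g. interactome proteins vs
#' the whole genome). Both one-sided hypergeometric tails are computed
#' per term and the smaller is reported with its direction;
#' Benjamini-Hochberg adjustment is applied across all tested terms.
#'
#' @param foreground Character vector of proteins, a subset of
#'   `background`.
#' @param background Character vector of universe proteins.
#' @param annotations A `go_annotations` data frame.
#' @param alpha FDR threshold recorded on the result (default 0.05).
#' @param parents Optional child -> parent table for annotation
#'   propagation before testing.
#' @return A data frame sorted by adjusted p: `go_term`, `aspect`,
#'   `observed`, `expected`, `direction`, `fold`, `p`, `adjusted_p`,
#'   `significant`, plus foreground/background sizes as attributes.
#' @export
enrich <- function(foreground, background, annotations, alpha = 0.05,
                   parents = NULL) {
  foreground <- unique(foreground); background <- unique(background)
  if (length(setdiff(foreground, background)) > 0)
    stop_validation("foreground must be a subset of the background")
  ann <- annotation_pairs(annotations)
  if (!is.null(parents)) ann <- propagate_annotations(ann, parents)
  ann <- ann[ann$protein_id %in% background, , drop = FALSE]
  terms <- sort(unique(ann$go_term))
  fg <- length(foreground); bg <- length(background)
  rows <- lapply(terms, function(tm) {
    members <- unique(ann$protein_id[ann$go_term == tm])
    K <- length(members)
    obs <- length(intersect(members, foreground))
    expd <- K * fg / bg
    p_enr <- hypergeometric_p(obs, fg, K, bg, "enriched")
    p_dep <- hypergeometric_p(obs, fg, K, bg, "depleted")
    dir <- if (p_enr <= p_dep) "enriched" else "depleted"
    data.frame(go_term = tm,
               aspect = ann$aspect[match(tm, ann$go_term)],
               observed = obs, expected = expd, direction = dir,
               fold = fold_change(obs, expd, dir),
               p = min(p_enr, p_dep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(go_term = character(0), aspect = character(0),
                      observed = integer(0), expected = numeric(0),
                      direction = character(0), fold = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$adjusted_p <= alpha
  out <- out[order(out$adjusted_p, out$p, out$go_term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "foreground_size") <- fg
  attr(out, "background_size") <- bg
  out
}
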