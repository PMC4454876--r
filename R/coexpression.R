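# Co-expression support for predicted interactions: M-values, per-edge
# Pearson correlation, a random-pair null, and the observed-vs-null test.
#
# M = log2(treatment / control) per gene per contrast. Interacting pairs
# are correlated across contrasts; the null draws non-edge protein pairs
# from the interactome.

#' Log2 treatment/control ratios
#'
#' Computes per-gene M-values, `M = log2(treatment / control)`, after
#' flooring both intensities at `floor` (standard practice to keep the
#' ratio finite on near-zero spots).
#'
#' @param treatment,control Positive numeric vectors of equal length.
#' @param floor Intensity floor applied before the ratio (default 1).
#' @return Numeric vector of M-values.
#' @export
m_values <- function(treatment, control, floor = 1) {
  if (length(treatment) != length(control))
    stop_validation("treatment and control vectors differ in length")
  t2 <- pmax(treatment, floor); c2 <- pmax(control, floor)
  bad <- which(!(t2 > 0) | !(c2 > 0))
  if (length(bad) > 0)
    stop_validation("nonpositive intensity after flooring at position(s) ",
                    paste(utils::head(bad, 3), collapse = ", "))
  log2(t2 / c2)
}

#' Global intensity normalization
#'
#' Scales each sample column so that its total intensity equals the mean
#' column total of the matrix, removing array-wide intensity differences
#' before ratios are formed.
#'
#' @param mat Numeric matrix of positive raw intensities (genes x samples).
#' @return The rescaled matrix; all column sums are equal afterwards.
#' @export
global_intensity_normalize <- function(mat) {
  totals <- colSums(mat)
  if (any(totals <= 0)) stop_validation("zero or negative column total")
  target <- mean(totals)
  sweep(mat, 2, totals / target, "/")
}

#' Convert an intensity matrix to M-values
#'
#' Applies global intensity normalization to the raw intensities, then
#' forms one M-value column per `<sample>__T` / `<sample>__C` pair.
#'
#' @param em An `expression_matrix` read in `intensities` mode.
#' @param floor Intensity floor passed to [m_values()].
#' @return An `expression_matrix` in `m_values` mode.
#' @export
as_m_values <- function(em, floor = 1) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$mode == "m_values") return(em)
  vals <- global_intensity_normalize(em$values)
  samples <- sort(unique(sub("__[TC]$", "", colnames(vals))))
  m <- sapply(samples, function(s)
    m_values(vals[, paste0(s, "__T")], vals[, paste0(s, "__C")], floor))
  m <- matrix(m, nrow = nrow(vals),
              dimnames = list(rownames(vals), samples))
  structure(list(values = m, mode = "m_values"), class = "expression_matrix")
}

#' Pearson correlation coefficient (computational form)
#'
#' Computes r with the raw-sums computational formula
#' `r = (n*sum(xy) - sum(x)*sum(y)) / sqrt((n*sum(x^2) - sum(x)^2) *
#' (n*sum(y^2) - sum(y)^2))`. Returns `NA` (an undefined-result signal,
#' not an error) when either vector has zero variance.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return r in \[-1, 1\], or `NA` for zero variance.
#' @export
pearson_cc <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_validation("vectors differ in length")
  if (n < 3) stop_validation("need at least 3 samples")
  sx <- sum(x); sy <- sum(y)
  den2 <- (n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2)
  if (!(den2 > 0)) return(NA_real_)
  r <- (n * sum(x * y) - sx * sy) / sqrt(den2)
  min(1, max(-1, r))
}

#' Default protein-to-gene id mapping
#'
#' Strips a trailing protein-model suffix (`_P01`-style, or the
#' transcript-style `_T01`/`_FGP001`) from protein ids so they match gene
#' ids on the expression platform. Override by supplying an explicit
#' named mapping to [edge_correlations()].
#'
#' @param proteins Character vector of protein ids.
#' @return Character vector of gene ids, named by protein.
#' @export
protein_to_gene <- function(proteins) {
  stats::setNames(sub("_(P|T|FGP)[0-9]+$", "", proteins), proteins)
}

map_genes <- function(proteins, mapping) {
  if (is.null(mapping)) return(protein_to_gene(proteins))
  unname(mapping[proteins]) |> stats::setNames(proteins)
}

edge_r_one <- function(gene_a, gene_b, vals) {
  if (is.na(gene_a) || is.na(gene_b) ||
      !(gene_a %in% rownames(vals)) || !(gene_b %in% rownames(vals)))
    return(list(r = NA_real_, status = "missing_gene"))
  r <- pearson_cc(vals[gene_a, ], vals[gene_b, ])
  if (is.na(r)) return(list(r = NA_real_, status = "zero_variance"))
  list(r = r, status = "ok")
}

#' Per-edge co-expression correlations
#'
#' Computes the Pearson correlation of M-value profiles for every
#' non-self edge of the network. Edges whose genes are absent from the
#' matrix or have zero variance are flagged undefined with a reason and
#' excluded from downstream tests, never imputed.
#'
#' @param network A `ppi_network`.
#' @param em An `expression_matrix` in `m_values` mode (or intensities;
#'   converted via [as_m_values()]).
#' @param mapping Optional named character vector protein id -> gene id;
#'   defaults to suffix stripping ([protein_to_gene()]).
#' @return A data frame: `protein_a`, `protein_b`, `gene_a`, `gene_b`,
#'   `r`, `n_samples`, `status`.
#' @export
edge_correlations <- function(network, em, mapping = NULL) {
  em <- as_m_values(em)
  e <- network$edges[network$edges$protein_a != network$edges$protein_b, ,
                     drop = FALSE]
  ga <- map_genes(e$protein_a, mapping)
  gb <- map_genes(e$protein_b, mapping)
  res <- mapply(edge_r_one, ga, gb, MoreArgs = list(vals = em$values),
                SIMPLIFY = FALSE)
  data.frame(protein_a = e$protein_a, protein_b = e$protein_b,
             gene_a = unname(ga), gene_b = unname(gb),
             r = vapply(res, `[[`, numeric(1), "r"),
             n_samples = ncol(em$values),
             status = vapply(res, `[[`, character(1), "status"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Random-pair null correlations
#'
#' Samples `k` distinct unordered non-edge pairs uniformly from the
#' interactome proteins that map into the expression matrix, and computes
#' their correlations exactly as [edge_correlations()] does. Reproducible
#' for a fixed seed.
#'
#' @param network A `ppi_network`.
#' @param em An `expression_matrix`.
#' @param k Number of random pairs.
#' @param seed Integer RNG seed (required; no silent nondeterminism).
#' @param mapping Optional protein -> gene mapping.
#' @return A data frame like [edge_correlations()]'s.
#' @export
random_pair_correlations <- function(network, em, k, seed, mapping = NULL) {
  if (k < 1) stop_validation("k must be >= 1")
  em <- as_m_values(em)
  genes <- map_genes(network$nodes, mapping)
  eligible <- network$nodes[!is.na(genes) & genes %in% rownames(em$values)]
  m <- length(eligible)
  e <- network$edges
  edge_keys <- pair_key(e$protein_a, e$protein_b)
  n_pairs <- choose(m, 2)
  if (n_pairs < 1) stop_validation("fewer than one eligible protein pair")
  # sample without replacement among non-edge unordered pairs
  picked <- with_seed(seed, {
    if (n_pairs <= 2e6) {
      idx <- utils::combn(m, 2)
      cp <- canonical_pair(eligible[idx[1, ]], eligible[idx[2, ]])
      keys <- pair_key(cp$protein_a, cp$protein_b)
      pool <- which(!(keys %in% edge_keys))
      if (length(pool) < k)
        stop_validation("fewer than k eligible non-edge pairs")
      sel <- sample(pool, k)
      cp[sel, , drop = FALSE]
    } else {
      seen <- character(0)
      out <- vector("list", k)
      got <- 0L
      while (got < k) {
        ij <- sample.int(m, 2)
        cp <- canonical_pair(eligible[ij[1]], eligible[ij[2]])
        key <- pair_key(cp$protein_a, cp$protein_b)
        if (key %in% seen || key %in% edge_keys) next
        seen <- c(seen, key)
        got <- got + 1L
        out[[got]] <- cp
      }
      do.call(rbind, out)
    }
  })
  ga <- map_genes(picked$protein_a, mapping)
  gb <- map_genes(picked$protein_b, mapping)
  res <- mapply(edge_r_one, ga, gb, MoreArgs = list(vals = em$values),
                SIMPLIFY = FALSE)
  data.frame(protein_a = picked$protein_a, protein_b = picked$protein_b,
             gene_a = unname(ga), gene_b = unname(gb),
             r = vapply(res, `[[`, numeric(1), "r"),
             n_samples = ncol(em$values),
             status = vapply(res, `[[`, character(1), "status"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare observed and null correlation distributions
#'
#' Tests whether interacting pairs are more co-expressed than random
#' pairs. The default is Welch's two-sample t-test (the random pairs are
#' not naturally paired with observed edges); a paired t-test is retained
#' as an option for method fidelity and requires equal lengths. Undefined
#' correlations are dropped first.
#'
#' @param observed,null Numeric vectors of correlation coefficients (NAs
#'   allowed, dropped).
#' @param mode `"welch"` (default) or `"paired"`.
#' @return A list: `t`, `p`, `mean_observed`, `mean_null`,
#'   `var_observed`, `var_null`, `n_observed`, `n_null`, `mode`.
#' @export
compare_distributions <- function(observed, null, mode = c("welch", "paired")) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (length(observed) != length(null))
      stop_validation("paired mode requires equal-length vectors")
    keep <- !(is.na(observed) | is.na(null))
    observed <- observed[keep]; null <- null[keep]
  } else {
    observed <- observed[!is.na(observed)]
    null <- null[!is.na(null)]
  }
  if (length(observed) < 2 || length(null) < 2)
    stop_validation("need at least 2 defined correlations per group")
  ht <- if (mode == "paired") {
    if (isTRUE(all.equal(observed, null))) {
      list(statistic = c(t = 0), p.value = 1)  # degenerate zero-difference case
    } else stats::t.test(observed, null, paired = TRUE)
  } else stats::t.test(observed, null, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_observed = mean(observed), mean_null = mean(null),
       var_observed = stats::var(observed), var_null = stats::var(null),
       n_observed = length(observed), n_null = length(null), mode = mode)
}

#' Histogram of correlation coefficients
#'
#' Bins defined r values at width 0.1 over \[-1, 1\].
#'
#' @param r Numeric vector (NAs dropped).
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
correlation_histogram <- function(r) {
  r <- r[!is.na(r)]
  breaks <- seq(-1, 1, by = 0.1)
  h <- hist(r, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  data.frame(lower = utils::head(breaks, -1), upper = breaks[-1],
             count = h$counts)
}
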