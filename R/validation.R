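# Overlap validation of a predicted interaction set against an
# independent experimental set, with an expected-by-chance model: among
# the V proteins common to both sets there are P = (V^2 + V)/2 possible
# unordered pairs (self-pairs included), and two random subsets of sizes
# n_a and n_b drawn from those P pairs share n_a * n_b / P pairs in
# expectation.

pair_df <- function(x) {
  stopifnot(is.data.frame(x), all(c("protein_a", "protein_b") %in% names(x)))
  unique(x[, c("protein_a", "protein_b")])
}

#' Restrict two interaction sets to their common proteins
#'
#' Finds the proteins present in both sets and keeps only the pairs whose
#' endpoints both lie in that common set.
#'
#' @param set_a,set_b Data frames of canonical pairs (`protein_a`,
#'   `protein_b`).
#' @return A list: `V` (common protein count), `restricted_a`,
#'   `restricted_b`.
#' @export
restrict_to_common <- function(set_a, set_b) {
  a <- pair_df(set_a); b <- pair_df(set_b)
  common <- intersect(unique(c(a$protein_a, a$protein_b)),
                      unique(c(b$protein_a, b$protein_b)))
  ra <- a[a$protein_a %in% common & a$protein_b %in% common, , drop = FALSE]
  rb <- b[b$protein_a %in% common & b$protein_b %in% common, , drop = FALSE]
  rownames(ra) <- rownames(rb) <- NULL
  list(V = length(common), restricted_a = ra, restricted_b = rb)
}

#' Expected overlap of two random pair subsets
#'
#' With V common proteins there are `P = (V^2 + V)/2` possible unordered
#' pairs (self-pairs included); two random subsets of sizes `n_a` and
#' `n_b` overlap in `n_a * n_b / P` pairs in expectation (the
#' hypergeometric mean).
#'
#' @param n_a,n_b Sizes of the two pair subsets (each `<= P`).
#' @param V Number of common proteins (`>= 1`).
#' @return The expected overlap count.
#' @export
expected_overlap <- function(n_a, n_b, V) {
  if (V < 1) stop_validation("V must be >= 1")
  P <- (V^2 + V) / 2
  if (n_a > P || n_b > P)
    stop_validation("subset size exceeds the number of possible pairs")
  n_a * n_b / P
}

#' Overlap report between predicted and experimental interaction sets
#'
#' Restricts both sets to their common proteins, counts the observed
#' pair overlap, compares it with the expected-by-chance overlap, and
#' tests the excess with a 1-degree-of-freedom chi-square on the 2-cell
#' partition (overlap / non-overlap) of the first set's restricted pairs
#' (no continuity correction).
#'
#' @param set_a,set_b Non-empty data frames of canonical pairs.
#' @return An `overlap_result` list: `V`, `P`, `n_a`, `n_b`, `observed`,
#'   `expected`, `fold`, `chi_square`, `p`.
#' @export
overlap_report <- function(set_a, set_b) {
  r <- restrict_to_common(set_a, set_b)
  if (r$V == 0) stop_validation("no proteins common to both sets")
  n_a <- nrow(r$restricted_a); n_b <- nrow(r$restricted_b)
  keys_a <- pair_key(r$restricted_a$protein_a, r$restricted_a$protein_b)
  keys_b <- pair_key(r$restricted_b$protein_a, r$restricted_b$protein_b)
  obs <- length(intersect(keys_a, keys_b))
  expd <- expected_overlap(n_a, n_b, r$V)
  chi <- if (expd > 0 && (n_a - expd) > 0)
    (obs - expd)^2 / expd + ((n_a - obs) - (n_a - expd))^2 / (n_a - expd)
  else NA_real_
  structure(list(V = r$V, P = (r$V^2 + r$V) / 2, n_a = n_a, n_b = n_b,
                 observed = obs, expected = expd,
                 fold = if (expd > 0) obs / expd else NA_real_,
                 chi_square = chi,
                 p = if (is.na(chi)) NA_real_
                     else stats::pchisq(chi, df = 1, lower.tail = FALSE)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap validation\n",
      sprintf("  common proteins (V): %d  possible pairs (P): %g\n", x$V, x$P),
      sprintf("  restricted pairs: %d vs %d\n", x$n_a, x$n_b),
      sprintf("  observed overlap: %d  expected by chance: %.2f\n",
              x$observed, x$expected),
      sprintf("  fold enrichment: %.2f  chi-square(1): %.2f  p: %.3g\n",
              x$fold, x$chi_square, x$p), sep = "")
  invisible(x)
}
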