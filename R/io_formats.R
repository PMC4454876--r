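# Readers and writers for every external format the pipeline touches.
# All tabular formats are tab-delimited UTF-8 with one header line;
# lines starting with '#' are comments.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(raw, "#")
  list(lines = raw[keep], lineno = which(keep))
}

# Parse a headered TSV into a data.frame of character columns, checking the
# required column set and tracking source line numbers.  Rows that fail
# `row_check(fields)` (which returns NULL or an error message) are either a
# parse error (on_error = "stop") or logged and skipped (on_error = "skip");
# rows are never silently dropped.
parse_tsv <- function(path, required, on_error = c("stop", "skip"),
                      row_check = NULL) {
  on_error <- match.arg(on_error)
  src <- read_tsv_lines(path)
  if (length(src$lines) == 0) stop_parse(path, ": missing header line")
  header <- strsplit(src$lines[[1]], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(required, header)
  if (length(missing) > 0)
    stop_parse(path, ": missing mandatory column(s): ",
               paste(missing, collapse = ", "))
  body <- src$lines[-1]
  lineno <- src$lineno[-1]
  nonempty <- nzchar(body)
  body <- body[nonempty]; lineno <- lineno[nonempty]
  fields <- strsplit(body, "\t", fixed = TRUE)
  rejected <- data.frame(line = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    reason <- NULL
    if (length(f) < length(header)) f <- c(f, rep("", length(header) - length(f)))
    if (length(f) > length(header))
      reason <- sprintf("expected %d fields, found %d", length(header), length(f))
    if (is.null(reason) && !is.null(row_check)) {
      names(f) <- header
      reason <- row_check(f)
    }
    if (is.null(reason)) {
      rows[[i]] <- f
    } else {
      msg <- sprintf("%s: line %d: %s", path, lineno[i], reason)
      if (on_error == "stop") stop_parse(msg)
      rejected <- rbind(rejected, data.frame(line = lineno[i], reason = reason,
                                             stringsAsFactors = FALSE))
      message("skipped ", msg)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    as.data.frame(matrix(character(0), ncol = length(header),
                         dimnames = list(NULL, header)),
                  stringsAsFactors = FALSE)
  } else {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  names(out) <- header
  attr(out, "rejected") <- rejected
  out
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read an ortholog cluster table
#'
#' Reads a five-column tab-delimited cluster table (`cluster_id`,
#' `species_tag`, `protein_id`, `inparalog_score`, `bootstrap_percent`)
#' in the style of pairwise ortholog-clustering output: each cluster spans
#' exactly two species (one reference species and the target species) and
#' lists every member protein with its inparalog score in \[0, 1\] and its
#' bootstrap support as an integer percent.
#'
#' @param path Path to the cluster TSV.
#' @param on_error `"stop"` (default) to raise a parse error naming the
#'   offending line, or `"skip"` to log and drop bad rows.
#' @return An `ortholog_clusters` data frame (one row per cluster member)
#'   with a `rejected` attribute listing any skipped lines.
#' @export
read_ortholog_table <- function(path, on_error = c("stop", "skip")) {
  req <- c("cluster_id", "species_tag", "protein_id",
           "inparalog_score", "bootstrap_percent")
  check <- function(f) {
    if (f[["cluster_id"]] == "" || f[["protein_id"]] == "" ||
        f[["species_tag"]] == "") return("empty cluster/species/protein id")
    sc <- num_or_na(f[["inparalog_score"]])
    bp <- num_or_na(f[["bootstrap_percent"]])
    if (is.na(sc) || is.na(bp)) return("non-numeric score or bootstrap")
    NULL
  }
  df <- parse_tsv(path, req, on_error, check)
  out <- data.frame(
    cluster_id = df$cluster_id,
    species_tag = df$species_tag,
    protein_id = trimws(df$protein_id),
    inparalog_score = num_or_na(df$inparalog_score),
    bootstrap_percent = as.integer(round(num_or_na(df$bootstrap_percent))),
    stringsAsFactors = FALSE)
  attr(out, "rejected") <- attr(df, "rejected")
  validate_clusters(out)
}

#' Validate a cluster member table
#'
#' Checks the cluster invariants: inparalog scores in \[0, 1\], bootstrap in
#' \[0, 100\], exactly two species per cluster with at least one member each,
#' and at least one full-score (1.0) member per species per cluster.
#'
#' @param members Data frame of cluster members as returned by
#'   [read_ortholog_table()].
#' @return The validated `ortholog_clusters` data frame (invisibly the same
#'   object, classed).
#' @export
validate_clusters <- function(members) {
  if (nrow(members) > 0) {
    bad <- members$inparalog_score < 0 | members$inparalog_score > 1
    if (any(bad))
      stop_validation("inparalog score outside [0,1] for protein(s) ",
                      paste(utils::head(members$protein_id[bad], 3), collapse = ", "))
    bad <- members$bootstrap_percent < 0 | members$bootstrap_percent > 100
    if (any(bad))
      stop_validation("bootstrap percent outside [0,100] for protein(s) ",
                      paste(utils::head(members$protein_id[bad], 3), collapse = ", "))
    nsp <- tapply(members$species_tag, members$cluster_id,
                  function(s) length(unique(s)))
    bad <- names(nsp)[nsp != 2L]
    if (length(bad) > 0)
      stop_validation("cluster(s) without exactly two species: ",
                      paste(utils::head(bad, 3), collapse = ", "))
    full <- tapply(members$inparalog_score == 1, paste(members$cluster_id,
                   members$species_tag, sep = "\r"), any)
    if (!all(full))
      stop_validation("cluster side(s) lacking a full-score (1.0) member: ",
                      paste(utils::head(names(full)[!full], 3), collapse = ", "))
  }
  class(members) <- c("ortholog_clusters", "data.frame")
  members
}

#' Read a reference interaction table
#'
#' Reads a six-column MITAB-like table of experimentally observed
#' interactions in a reference species: `species`, `id_a`, `id_b`,
#' `method`, `source_db`, `publication` (the last two may be empty).
#' Protein ids are stripped of surrounding whitespace but the raw id order
#' is preserved for provenance; duplicate rows are kept — deduplication
#' happens after transfer, not at read time.
#'
#' @inheritParams read_ortholog_table
#' @return A `reference_interactions` data frame, one row per support
#'   record.
#' @export
read_reference_interactions <- function(path, on_error = c("stop", "skip")) {
  req <- c("species", "id_a", "id_b", "method", "source_db", "publication")
  check <- function(f) {
    if (trimws(f[["id_a"]]) == "" || trimws(f[["id_b"]]) == "")
      return("empty protein id")
    if (f[["species"]] == "") return("empty species tag")
    NULL
  }
  df <- parse_tsv(path, req, on_error, check)
  out <- data.frame(
    species = df$species,
    id_a = trimws(df$id_a),
    id_b = trimws(df$id_b),
    method = df$method,
    source_db = df$source_db,
    publication = df$publication,
    stringsAsFactors = FALSE)
  attr(out, "rejected") <- attr(df, "rejected")
  class(out) <- c("reference_interactions", "data.frame")
  out
}

#' Read a GO annotation table
#'
#' Reads a three-column table (`protein_id`, `go_term`, `aspect`) mapping
#' proteins to GO terms. Aspects must be one of `P` (biological process),
#' `F` (molecular function) or `C` (cellular component). Duplicate
#' (protein, term, aspect) rows collapse to one — annotations are sets.
#'
#' @inheritParams read_ortholog_table
#' @return A `go_annotations` data frame with one row per distinct
#'   (protein, term, aspect) assignment.
#' @export
read_go_annotations <- function(path, on_error = c("stop", "skip")) {
  req <- c("protein_id", "go_term", "aspect")
  check <- function(f) {
    if (!(f[["aspect"]] %in% c("P", "F", "C")))
      return(paste0("unknown GO aspect '", f[["aspect"]], "'"))
    if (f[["protein_id"]] == "" || f[["go_term"]] == "")
      return("empty protein or term id")
    NULL
  }
  df <- parse_tsv(path, req, on_error, check)
  out <- unique(data.frame(protein_id = df$protein_id, go_term = df$go_term,
                           aspect = df$aspect, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "rejected") <- attr(df, "rejected")
  class(out) <- c("go_annotations", "data.frame")
  out
}

#' Read an expression matrix
#'
#' Reads a genes-by-samples expression table whose first column holds gene
#' ids. In `m_values` mode the remaining columns are already log2
#' treatment/control ratios. In `intensities` mode the columns must come in
#' treatment/control pairs named `<sample>__T` and `<sample>__C`; M-values
#' are computed later by [as_m_values()], not at read time.
#'
#' @param path Path to the TSV.
#' @param mode `"m_values"` (default) or `"intensities"`.
#' @return An `expression_matrix` object: a list with the numeric `values`
#'   matrix (genes x columns) and the `mode`.
#' @export
read_expression_matrix <- function(path, mode = c("m_values", "intensities")) {
  mode <- match.arg(mode)
  src <- read_tsv_lines(path)
  if (length(src$lines) == 0) stop_parse(path, ": missing header line")
  header <- strsplit(src$lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) stop_parse(path, ": need a gene id column plus data")
  samples <- header[-1]
  body <- src$lines[-1]; lineno <- src$lineno[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  genes <- character(length(fields))
  vals <- matrix(NA_real_, nrow = length(fields), ncol = length(samples))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != length(header))
      stop_parse(path, ": line ", lineno[i], ": expected ", length(header),
                 " fields, found ", length(f))
    genes[i] <- f[1]
    v <- num_or_na(f[-1])
    if (anyNA(v))
      stop_parse(path, ": line ", lineno[i], ": non-numeric value in column '",
                 samples[which(is.na(v))[1]], "'")
    vals[i, ] <- v
  }
  if (anyDuplicated(genes))
    stop_validation("duplicate gene id(s): ",
                    paste(unique(genes[duplicated(genes)]), collapse = ", "))
  rownames(vals) <- genes
  colnames(vals) <- samples
  if (mode == "intensities") {
    trt <- grepl("__T$", samples)
    ctl <- grepl("__C$", samples)
    if (!all(trt | ctl))
      stop_validation("intensities mode requires __T/__C column suffixes")
    base_t <- sort(sub("__T$", "", samples[trt]))
    base_c <- sort(sub("__C$", "", samples[ctl]))
    if (!identical(base_t, base_c))
      stop_validation("unpaired treatment/control column(s): ",
                      paste(c(setdiff(base_t, base_c), setdiff(base_c, base_t)),
                            collapse = ", "))
  }
  structure(list(values = vals, mode = mode),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "columns (", x$mode, ")\n")
  invisible(x)
}

#' Export a network in SIF format with attribute tables
#'
#' Writes one `A<TAB>pp<TAB>B` line per edge (canonical order; self-loops
#' as `A pp A`) for import into graph visualization software, plus two
#' companion tab-delimited tables next to the SIF file: edge attributes
#' (CV, number of supporting species, confidence bin) and node attributes
#' (degree, hub class).
#'
#' @param network A `ppi_network` from [build_network()].
#' @param path Output SIF path; the companion files get
#'   `_edge_attributes.tsv` / `_node_attributes.tsv` suffixes in place of
#'   the extension.
#' @return Invisibly, the three paths written.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "ppi_network"))
  e <- network$edges
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(paste(e$protein_a, "pp", e$protein_b, sep = "\t"), tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  stem <- sub("\\.[^./]*$", "", path)
  epath <- paste0(stem, "_edge_attributes.tsv")
  npath <- paste0(stem, "_node_attributes.tsv")
  write_tsv_atomic(data.frame(protein_a = e$protein_a, protein_b = e$protein_b,
                              cv = e$cv, n_species = e$n_species, bin = e$bin,
                              stringsAsFactors = FALSE), epath)
  ns <- node_stats(network)
  write_tsv_atomic(ns, npath)
  invisible(c(sif = path, edge_attributes = epath, node_attributes = npath))
}

#' Read a SIF edge list back into canonical pairs
#'
#' Reads a SIF file written by [write_sif()] (or any `A pp B` SIF with one
#' target per line) and returns the canonical edge set.
#'
#' @param path SIF path.
#' @return A data frame of canonical `protein_a` / `protein_b` pairs.
#' @export
read_sif <- function(path) {
  src <- read_tsv_lines(path)
  if (length(src$lines) == 0)
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(src$lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3)
  if (length(bad) > 0)
    stop_parse(path, ": line ", src$lineno[bad[1]], ": expected 3 SIF fields")
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 3)
  unique(canonical_pair(a, b))
}
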