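# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Byte-order sort key: hexadecimal expansion of the raw bytes of a string.
# Comparing these keys with the ordinary string operators reproduces strict
# byte-order (C locale) comparison regardless of the session locale, because
# the keys only contain the characters 0-9a-f.
byte_key <- function(x) {
  vapply(x, function(s) paste(format(as.hexmode(as.integer(charToRaw(s))),
                                     width = 2), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# TRUE where a sorts strictly after b in byte order.
byte_gt <- function(a, b) byte_key(a) > byte_key(b)

# Run code with a private, restorable RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Atomic text-table writer: write to a temp file in the destination
# directory, then rename over the target.
write_tsv_atomic <- function(df, path, comments = character(0)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wt", encoding = "UTF-8")
  ok <- FALSE
  tryCatch({
    for (cm in comments) writeLines(paste0("# ", cm), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    ok <- TRUE
  }, finally = close(con))
  if (!ok) {
    unlink(tmp)
    stop("failed to write ", path, call. = FALSE)
  }
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not move temporary file onto ", path, call. = FALSE)
  }
  invisible(path)
}

stop_validation <- function(...) {
  stop(structure(class = c("interologr_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("interologr_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Canonicalize an interacting protein pair
#'
#' Orders an unordered protein pair into the canonical form used throughout
#' the package: the lexicographically larger identifier (byte-order
#' comparison) is reported as protein A and the smaller as protein B, so
#' that an interaction and its mirror image collapse onto one record.
#' Self-interactions are fixed points.
#'
#' @param a,b Character vectors of protein identifiers (recycled to a
#'   common length). Identifiers are opaque, case-sensitive strings; empty
#'   strings are rejected.
#' @return A data frame with columns `protein_a` (larger id) and
#'   `protein_b` (smaller id).
#' @examples
#' canonical_pair("GRMZM2G008327_P01", "GRMZM2G061287_P01")
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(is.na(a) | is.na(b) | a == "" | b == ""))
    stop_validation("protein ids must be non-empty strings")
  swap <- byte_gt(b, a)
  pa <- ifelse(swap, b, a)
  pb <- ifelse(swap, a, b)
  data.frame(protein_a = pa, protein_b = pb, stringsAsFactors = FALSE)
}

# Single-string key for a canonical pair; \r never occurs in protein ids.
pair_key <- function(a, b) paste(a, b, sep = "\r")
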