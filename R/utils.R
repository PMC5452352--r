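# Internal helpers shared across modules.

#' Run code with a fixed RNG seed, restoring RNG state afterwards
#'
#' Thin wrapper around [withr::with_seed()] so that every stochastic
#' operation in the package can take an explicit `seed` argument without
#' disturbing the caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Derive a child seed from a base seed and a stage offset, staying inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset) %% 2147483647)
}

#' Stable content-derived identifier
#'
#' MD5 of the key string (first 12 hex digits), so identifiers are stable
#' across runs, platforms and R sessions.
#'
#' @param keys Character vector of key strings.
#' @return Character vector of 12-hex-digit identifiers.
#' @keywords internal
content_id <- function(keys) {
  vapply(keys, function(k) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    writeChar(k, f, eos = NULL)
    substr(unname(tools::md5sum(f)), 1L, 12L)
  }, character(1), USE.NAMES = FALSE)
}

# Exon-chain encoding used in event catalogs: "start-end,start-end" with
# 0-based half-open coordinates.
encode_form <- function(exons) {
  paste(sprintf("%d-%d", exons[, 1], exons[, 2]), collapse = ",")
}

decode_form <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
  colnames(m) <- c("start", "end")
  m
}

# Deterministic TSV writer: tab-separated, header, no quoting.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-separated table with a required schema
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @return A `data.frame`.
#' @export
read_table_schema <- function(path, required = character()) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  df
}
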