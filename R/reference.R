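#' Chemical reference table
#'
#' Ground-truth astaxanthin concentrations (micrograms of astaxanthin per
#' gram of fish) determined chemically in duplicate. The working
#' concentration for each sample is the mean of the two replicates; the
#' replicates are retained for audit.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param replicate_a,replicate_b numeric non-negative replicate
#'   concentrations (ug/g).
#' @return A data frame of class `reference_table` with columns
#'   `sample_id`, `replicate_a`, `replicate_b`, `concentration`.
#' @export
reference_table <- function(sample_id, replicate_a, replicate_b) {
  sample_id <- as.character(sample_id)
  a <- as.numeric(replicate_a)
  b <- as.numeric(replicate_b)
  n <- length(sample_id)
  if (length(a) != n || length(b) != n) {
    stop("sample_id, replicate_a, replicate_b must have equal length")
  }
  if (anyNA(a) || anyNA(b)) stop("replicate concentrations must be numeric")
  if (any(a < 0) || any(b < 0)) stop("concentrations must be >= 0")
  if (anyDuplicated(sample_id)) stop("sample_ids must be unique")
  out <- data.frame(sample_id = sample_id, replicate_a = a, replicate_b = b,
                    concentration = (a + b) / 2,
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Read a chemical reference table from CSV
#'
#' Expects a header `sample_id,replicate_a,replicate_b`; the working
#' concentration (mean of the replicates) is computed on load.
#'
#' @param path CSV path.
#' @return A [reference_table].
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate_a", "replicate_b")
  if (!all(need %in% names(df))) {
    stop("parse error: reference CSV must have columns ",
         paste(need, collapse = ", "))
  }
  a <- suppressWarnings(as.numeric(df$replicate_a))
  b <- suppressWarnings(as.numeric(df$replicate_b))
  if (anyNA(a) || anyNA(b)) stop("parse error: non-numeric concentration")
  if (any(a < 0) || any(b < 0)) stop("parse error: negative concentration")
  reference_table(df$sample_id, a, b)
}

#' Write a chemical reference table to CSV
#'
#' @param table a [reference_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(table, path) {
  utils::write.csv(
    table[, c("sample_id", "replicate_a", "replicate_b")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
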