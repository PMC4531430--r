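#' Tags-per-million normalization for small-RNA counts
#'
#' Scales each raw tag count by its sample's total mapped reads:
#' `TPM(f, s) = count(f, s) * 1e6 / N(s)`. This is the tag-count reading
#' of "transcripts per million" used for fixed-length small-RNA tags;
#' no length term is involved, so when the library size equals the column
#' sum each TPM column sums to exactly one million.
#'
#' @param table a [count_table()] with `feature_class = "miRNA"`.
#' @return A `normalized_table`: list with `values` (matrix of TPM),
#'   `feature_ids`, `sample_ids`, `method = "TPM"`.
#' @export
tpm_normalize <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (!identical(table$feature_class, "miRNA"))
    stop("tpm_normalize is defined for miRNA tag tables; use rpkm_normalize for genes")
  if (any(table$library_sizes == 0)) stop("library size of zero")
  values <- sweep(table$counts, 2, table$library_sizes, "/") * 1e6
  structure(list(values = values, feature_ids = table$feature_ids,
                 sample_ids = table$sample_ids, method = "TPM"),
            class = "normalized_table")
}

#' RPKM normalization for gene counts
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `RPKM(f, s) = count(f, s) * 1e9 / (N(s) * L(f))` with `L(f)` the feature
#' length in nucleotides. RPKM is inversely proportional to both library
#' size and feature length.
#'
#' @param table a [count_table()] with `feature_class = "gene"` and
#'   feature lengths present.
#' @return A `normalized_table` with `method = "RPKM"`.
#' @export
rpkm_normalize <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (!identical(table$feature_class, "gene"))
    stop("rpkm_normalize is defined for gene tables")
  if (is.null(table$feature_lengths)) stop("feature lengths are required")
  if (any(table$feature_lengths == 0)) stop("feature length of zero")
  values <- sweep(table$counts, 2, table$library_sizes, "/")
  values <- sweep(values, 1, table$feature_lengths, "/") * 1e9
  structure(list(values = values, feature_ids = table$feature_ids,
                 sample_ids = table$sample_ids, method = "RPKM"),
            class = "normalized_table")
}

#' Normalize a count table by its feature class
#'
#' Dispatches to [tpm_normalize()] for miRNA tag tables and
#' [rpkm_normalize()] for gene tables.
#'
#' @param table a [count_table()].
#' @return A `normalized_table`.
#' @export
normalize_counts <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (identical(table$feature_class, "miRNA")) tpm_normalize(table)
  else rpkm_normalize(table)
}

#' Write a normalized table as TSV with a method header comment
#'
#' @param norm a `normalized_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_normalized_table <- function(norm, path) {
  stopifnot(inherits(norm, "normalized_table"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# method=", norm$method), con)
  df <- cbind(data.frame(feature_id = norm$feature_ids,
                         stringsAsFactors = FALSE),
              as.data.frame(norm$values, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
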