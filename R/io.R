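# Readers and writers for the tabular dialect used throughout: TSV, UTF-8,
# '#'-prefixed comment lines skipped, identifiers whitespace-trimmed but
# case-preserved (miRNA star names such as hsa-miR-22* kept verbatim).

read_tsv_strict <- function(path, required_cols) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(NULL)
  tab <- utils::read.delim(text = lines, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  missing <- setdiff(required_cols, names(tab))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  tab
}

#' Read a feature count table from TSV
#'
#' Expects a header row `feature_id[<TAB>length]<TAB><sample1>...`; a
#' `length` column is required for gene tables and must be absent for
#' miRNA tables. `#`-prefixed lines are skipped.
#'
#' @param path TSV file path.
#' @param feature_class `"miRNA"` or `"gene"`.
#' @param library_sizes `"column-sum"` or a named vector of total mapped
#'   reads (see [count_table()]).
#' @return A [count_table()].
#' @export
read_count_table <- function(path, feature_class = c("miRNA", "gene"),
                             library_sizes = "column-sum") {
  feature_class <- match.arg(feature_class)
  tab <- read_tsv_strict(path, "feature_id")
  if (is.null(tab)) stop(path, ": empty count table")
  has_len <- "length" %in% names(tab)
  if (feature_class == "gene" && !has_len)
    stop(path, ": gene count tables require a 'length' column")
  ids <- trimws(as.character(tab$feature_id))
  if (anyDuplicated(ids))
    stop(path, ": duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sample_cols <- setdiff(names(tab), c("feature_id", "length"))
  if (length(sample_cols) == 0) stop(path, ": no sample columns")
  counts <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    bad <- which(apply(tab[, sample_cols, drop = FALSE], 1, function(r)
      any(!is.finite(suppressWarnings(as.numeric(r))) |
          suppressWarnings(as.numeric(r)) < 0 |
          suppressWarnings(as.numeric(r)) != round(suppressWarnings(as.numeric(r))))))[1]
    stop(sprintf("%s: non-integer or negative count in row for '%s'",
                 path, ids[bad]))
  }
  rownames(counts) <- ids
  lens <- NULL
  if (has_len && feature_class == "gene")
    lens <- stats::setNames(as.numeric(tab$length), ids)
  count_table(counts, feature_class = feature_class,
              library_sizes = library_sizes, feature_lengths = lens)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]; gene tables regain their `length`
#' column so that read/write round-trips are lossless.
#'
#' @param table a [count_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(feature_id = table$feature_ids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (identical(table$feature_class, "gene"))
    df$length <- as.integer(table$feature_lengths)
  df <- cbind(df, as.data.frame(table$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read one miRNA target prediction source
#'
#' Each source file is a two-column TSV `mirna_id<TAB>gene_id`; duplicate
#' pairs within a file are collapsed. An empty file yields an empty
#' evidence table with a warning (a predictor may legitimately predict
#' nothing for the queried miRNAs).
#'
#' @param path TSV file path.
#' @param source_name label for this prediction source.
#' @return Data frame with columns `mirna_id`, `gene_id`, `source`.
#' @export
read_prediction_source <- function(path, source_name) {
  tab <- read_tsv_strict(path, c("mirna_id", "gene_id"))
  if (is.null(tab) || nrow(tab) == 0) {
    warning(path, ": empty prediction source '", source_name, "'")
    return(data.frame(mirna_id = character(), gene_id = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(mirna_id = trimws(as.character(tab$mirna_id)),
                    gene_id = trimws(as.character(tab$gene_id)),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out$source <- source_name
  rownames(out) <- NULL
  out
}

#' Merge prediction evidence across sources
#'
#' Collapses per-source (miRNA, gene) rows into one row per pair carrying
#' the set of supporting sources.
#'
#' @param ... data frames from [read_prediction_source()] (or one list of
#'   them).
#' @return Data frame with columns `mirna_id`, `gene_id`, `sources`
#'   (list column of source names), `n_sources`.
#' @export
merge_evidence <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !is.data.frame(parts[[1]]))
    parts <- parts[[1]]
  all_rows <- do.call(rbind, parts)
  if (is.null(all_rows) || nrow(all_rows) == 0)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      n_sources = integer(), stringsAsFactors = FALSE))
  key <- paste(all_rows$mirna_id, all_rows$gene_id, sep = "\r")
  src <- split(all_rows$source, key)
  src <- lapply(src, function(s) sort(unique(s)))
  keys <- names(src)
  parts2 <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(mirna_id = vapply(parts2, `[[`, "", 1),
                    gene_id = vapply(parts2, `[[`, "", 2),
                    n_sources = lengths(src),
                    stringsAsFactors = FALSE)
  out$sources <- unname(src)
  out <- out[order(out$mirna_id, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Lines are `set_id<TAB>description<TAB>gene1<TAB>gene2...`; a line with
#' fewer than three fields is a format error.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("%s: GMT line %d has fewer than 3 fields", path, bad[1]))
  ids <- trimws(vapply(fields, `[[`, "", 1))
  descs <- trimws(vapply(fields, `[[`, "", 2))
  sets <- lapply(fields, function(f) trimws(f[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, names_ = stats::setNames(descs, ids))
}

#' Write a gene-set collection as GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$set_names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a regulatory network to disk
#'
#' Two dialects: `"sif"` writes `mirna<TAB>represses<TAB>gene` lines (and
#' `gene<TAB>member_of<TAB>pathway` for tripartite networks); `"edge-table"`
#' writes a typed TSV of edges. Node order is lexicographic so identical
#' networks serialize identically.
#'
#' @param network a `regulatory_network` (see [build_network()]) or
#'   tripartite network from [assemble_tripartite()].
#' @param path output file path.
#' @param dialect `"sif"` or `"edge-table"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, dialect = c("sif", "edge-table")) {
  dialect <- match.arg(dialect)
  edges <- network$edges
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  if (dialect == "sif") {
    if (nrow(edges) == 0) {
      writeLines(character(), path)
      return(invisible(path))
    }
    writeLines(paste(edges$from, edges$relation, edges$to, sep = "\t"), path)
  } else {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a results data frame as TSV
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  listcols <- vapply(df, is.list, TRUE)
  df[listcols] <- lapply(df[listcols], function(col)
    vapply(col, function(x) paste(x, collapse = ","), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
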