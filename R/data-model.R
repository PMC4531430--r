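#' Construct a validated count table
#'
#' A `count_table` holds raw tag counts for one feature class (miRNA tags or
#' genes) across samples, together with per-sample library sizes (total
#' mapped reads, which may exceed the column sums) and, for genes, feature
#' lengths in nucleotides used by RPKM normalization.
#'
#' @param counts integer matrix, features x samples, with unique non-empty
#'   dimnames. All entries must be non-negative integers.
#' @param feature_class `"miRNA"` or `"gene"`.
#' @param library_sizes named positive numeric vector of total mapped reads
#'   per sample, or the string `"column-sum"` to use per-sample column
#'   totals.
#' @param feature_lengths named positive integer vector of feature lengths
#'   in nucleotides. Required when `feature_class = "gene"`, disallowed for
#'   miRNA tag tables.
#' @return An object of class `count_table` with elements `counts`,
#'   `feature_ids`, `sample_ids`, `library_sizes`, `feature_lengths`,
#'   `feature_class`.
#' @export
count_table <- function(counts, feature_class = c("miRNA", "gene"),
                        library_sizes = "column-sum",
                        feature_lengths = NULL) {
  feature_class <- match.arg(feature_class)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must carry feature and sample names")
  feature_ids <- trimws(rownames(counts))
  sample_ids <- trimws(colnames(counts))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  storage.mode(counts) <- "double"
  rownames(counts) <- feature_ids
  colnames(counts) <- sample_ids

  if (identical(library_sizes, "column-sum")) {
    library_sizes <- colSums(counts)
  } else {
    if (is.null(names(library_sizes)))
      stop("library_sizes must be named by sample")
    missing <- setdiff(sample_ids, names(library_sizes))
    if (length(missing))
      stop("library_sizes missing for sample(s): ",
           paste(missing, collapse = ", "))
    library_sizes <- library_sizes[sample_ids]
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    stop("library sizes must be positive")

  if (feature_class == "gene") {
    if (is.null(feature_lengths))
      stop("feature_lengths are required for gene count tables")
    if (is.null(names(feature_lengths)))
      stop("feature_lengths must be named by feature")
    missing <- setdiff(feature_ids, names(feature_lengths))
    if (length(missing))
      stop("feature_lengths missing for feature(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    feature_lengths <- feature_lengths[feature_ids]
    if (any(!is.finite(feature_lengths)) || any(feature_lengths <= 0))
      stop("feature lengths must be positive")
  } else if (!is.null(feature_lengths)) {
    stop("feature_lengths are only meaningful for gene tables")
  }

  structure(
    list(counts = counts, feature_ids = feature_ids, sample_ids = sample_ids,
         library_sizes = library_sizes, feature_lengths = feature_lengths,
         feature_class = feature_class),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d features x %d samples\n",
              x$feature_class, length(x$feature_ids), length(x$sample_ids)))
  cat("library sizes:",
      paste(sprintf("%s=%g", x$sample_ids, x$library_sizes), collapse = ", "),
      "\n")
  invisible(x)
}

#' Define condition/reference sample pairings
#'
#' Each pair compares one condition (stem-like) sample against its matched
#' reference (parental cancer) sample; a sample may appear in at most one
#' pair.
#'
#' @param pairs data frame (or list of 2-vectors) with columns
#'   `condition_sample`, `reference_sample`, optionally `pair_id`.
#' @param condition_label,reference_label free-text labels recorded with
#'   the pairing.
#' @return An object of class `sample_pairing`.
#' @export
sample_pairing <- function(pairs, condition_label = "stem",
                           reference_label = "cancer") {
  if (!is.data.frame(pairs))
    pairs <- do.call(rbind, lapply(pairs, function(p)
      data.frame(condition_sample = p[[1]], reference_sample = p[[2]])))
  if (!all(c("condition_sample", "reference_sample") %in% names(pairs)))
    stop("pairs need condition_sample and reference_sample columns")
  if (nrow(pairs) < 1) stop("at least one sample pair is required")
  if (is.null(pairs$pair_id))
    pairs$pair_id <- paste0("pair", seq_len(nrow(pairs)))
  all_samples <- c(pairs$condition_sample, pairs$reference_sample)
  if (anyDuplicated(all_samples))
    stop("each sample may appear in at most one pair: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  structure(list(pairs = pairs[, c("pair_id", "condition_sample",
                                   "reference_sample")],
                 condition_label = condition_label,
                 reference_label = reference_label),
            class = "sample_pairing")
}

#' Analysis thresholds
#'
#' Bundles the filtering thresholds used across the pipeline: the minimum
#' absolute log2 fold change and maximum FDR for a differential call, the
#' minimum number of prediction sources supporting a consensus interaction,
#' the enrichment significance level, and the pseudocount added to
#' normalized values before forming log ratios.
#'
#' @param min_abs_log2fc minimum |log2 fold change| for a call (default 1).
#' @param max_fdr maximum BH-adjusted p-value for a call (default 0.01).
#' @param min_sources minimum supporting prediction sources (default 2).
#' @param enrichment_alpha pathway-enrichment significance level
#'   (default 0.05).
#' @param pseudocount added to both normalized values in the fold change
#'   (default 0.5).
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(min_abs_log2fc = 1.0, max_fdr = 0.01,
                             min_sources = 2L, enrichment_alpha = 0.05,
                             pseudocount = 0.5) {
  stopifnot(min_abs_log2fc > 0, pseudocount > 0,
            min_sources >= 1, min_sources == round(min_sources))
  if (max_fdr <= 0 || max_fdr > 1) stop("max_fdr must lie in (0, 1]")
  if (enrichment_alpha <= 0 || enrichment_alpha > 1)
    stop("enrichment_alpha must lie in (0, 1]")
  structure(list(min_abs_log2fc = min_abs_log2fc, max_fdr = max_fdr,
                 min_sources = as.integer(min_sources),
                 enrichment_alpha = enrichment_alpha,
                 pseudocount = pseudocount),
            class = "threshold_config")
}

#' Gene-set collection
#'
#' @param sets named list of character vectors of gene ids; names are
#'   pathway ids.
#' @param names_ named character vector of human-readable pathway names
#'   (defaults to the ids).
#' @param background optional explicit gene universe; defaults (at
#'   enrichment time) to the union of all sets.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, names_ = NULL, background = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique ids")
  sets <- lapply(sets, function(g) unique(trimws(g)))
  if (any(lengths(sets) == 0)) stop("gene sets must be non-empty")
  if (is.null(names_)) names_ <- stats::setNames(names(sets), names(sets))
  structure(list(sets = sets, set_names = names_,
                 background = if (is.null(background)) NULL
                              else unique(trimws(background))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}
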