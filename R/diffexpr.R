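#' Call differential expression for one condition/reference sample pair
#'
#' For every feature, computes the exact Poisson tag-count p-value from
#' the raw counts and library sizes ([poisson_tagcount_p()]), adjusts
#' p-values with [bh_adjust()] across all features of the table, and forms
#' `log2fc = log2((condition_normalized + pseudocount) /
#' (reference_normalized + pseudocount))`, with normalized values TPM for
#' miRNA tags and RPKM for genes. A feature is called `up` when
#' `log2fc >= min_abs_log2fc` and `fdr <= max_fdr`, `down` when
#' `log2fc <= -min_abs_log2fc` and `fdr <= max_fdr`, else `none`;
#' both boundaries are inclusive.
#'
#' @param table a [count_table()].
#' @param condition_sample,reference_sample sample ids in `table`.
#' @param thresholds a [threshold_config()].
#' @param pair_id label recorded in the result (default
#'   `"condition_vs_reference"`).
#' @return Data frame with one row per feature: `feature_id`, `pair_id`,
#'   `x` (condition count), `y` (reference count), `N1`, `N2`, `log2fc`,
#'   `p_value`, `fdr`, `direction`.
#' @export
call_de <- function(table, condition_sample, reference_sample,
                    thresholds = threshold_config(), pair_id = NULL) {
  stopifnot(inherits(table, "count_table"),
            inherits(thresholds, "threshold_config"))
  missing <- setdiff(c(condition_sample, reference_sample), table$sample_ids)
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  if (is.null(pair_id))
    pair_id <- paste0(condition_sample, "_vs_", reference_sample)

  x <- table$counts[, condition_sample]
  y <- table$counts[, reference_sample]
  N1 <- table$library_sizes[[condition_sample]]
  N2 <- table$library_sizes[[reference_sample]]

  norm <- normalize_counts(table)
  nx <- norm$values[, condition_sample]
  ny <- norm$values[, reference_sample]
  ps <- thresholds$pseudocount
  log2fc <- log2((nx + ps) / (ny + ps))

  # The test is formulated as the predictive distribution of the second
  # count given the first; condition counts play the role of x.
  p <- poisson_tagcount_p(x, y, N1, N2)
  fdr <- bh_adjust(p)

  direction <- rep("none", length(x))
  sig <- fdr <= thresholds$max_fdr
  direction[sig & log2fc >= thresholds$min_abs_log2fc] <- "up"
  direction[sig & log2fc <= -thresholds$min_abs_log2fc] <- "down"

  data.frame(feature_id = table$feature_ids, pair_id = pair_id,
             x = unname(x), y = unname(y), N1 = N1, N2 = N2,
             log2fc = unname(log2fc), p_value = unname(p),
             fdr = unname(fdr), direction = direction,
             stringsAsFactors = FALSE)
}

#' Call differential expression for every pair in a pairing
#'
#' @param table a [count_table()].
#' @param pairing a [sample_pairing()].
#' @param thresholds a [threshold_config()].
#' @return Data frame of stacked [call_de()] results, one block per pair.
#' @export
call_de_pairs <- function(table, pairing, thresholds = threshold_config()) {
  stopifnot(inherits(pairing, "sample_pairing"))
  out <- lapply(seq_len(nrow(pairing$pairs)), function(i) {
    p <- pairing$pairs[i, ]
    call_de(table, p$condition_sample, p$reference_sample, thresholds,
            pair_id = p$pair_id)
  })
  do.call(rbind, out)
}

#' Features consistently regulated across two sample pairs
#'
#' Retains features called in the same direction in both pairs; features
#' discordant between pairs, or called in only one, are excluded from
#' both sets. Both call sets must cover the same feature universe.
#'
#' @param calls_pair1,calls_pair2 data frames from [call_de()] covering
#'   identical feature sets.
#' @return A `consistent_sets` object: list with character vectors `up`
#'   and `down` (disjoint by construction).
#' @export
consistent_features <- function(calls_pair1, calls_pair2) {
  u1 <- calls_pair1$feature_id
  u2 <- calls_pair2$feature_id
  if (!setequal(u1, u2)) {
    diff <- c(setdiff(u1, u2), setdiff(u2, u1))
    stop("call sets cover different features: ",
         paste(utils::head(diff, 10), collapse = ", "))
  }
  d1 <- stats::setNames(calls_pair1$direction, u1)
  d2 <- stats::setNames(calls_pair2$direction, u2)[u1]
  structure(list(up = sort(u1[d1 == "up" & d2 == "up"]),
                 down = sort(u1[d1 == "down" & d2 == "down"])),
            class = "consistent_sets")
}

#' @export
print.consistent_sets <- function(x, ...) {
  cat(sprintf("consistent_sets: %d up, %d down\n",
              length(x$up), length(x$down)))
  invisible(x)
}
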