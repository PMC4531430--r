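#' Pathway over-representation of a gene set
#'
#' One-sided Fisher (hypergeometric) enrichment of a query gene set --
#' typically one miRNA's candidate targets -- against each pathway of a
#' collection. With `n` query genes, `K` pathway genes, universe `N` and
#' overlap `k`, the p-value is the hypergeometric upper tail
#' `P(X >= k)`. Pathways with no overlap are omitted (their one-sided p
#' is 1 by construction). The optional EASE variant recomputes the tail
#' with the overlap reduced by one, a deliberately conservative score
#' used by the DAVID annotation service.
#'
#' @param query character vector of gene ids (must lie in the
#'   background).
#' @param collection a [gene_set_collection()].
#' @param background optional explicit gene universe; defaults to the
#'   collection's recorded background, else the union of its sets.
#' @param alpha significance level for the `significant` flag, inclusive
#'   at the boundary (default 0.05).
#' @param ease if `TRUE`, use the EASE score (overlap - 1).
#' @param mirna_id optional label copied into every result row.
#' @return Data frame sorted by p-value: `mirna_id`, `pathway_id`,
#'   `pathway_name`, `overlap_count`, `query_size`, `pathway_size`,
#'   `background_size`, `p_value`, `significant`, and list column
#'   `overlap_genes`.
#' @export
enrich <- function(query, collection, background = NULL, alpha = 0.05,
                   ease = FALSE, mirna_id = NA_character_) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(background)) background <- collection$background
  if (is.null(background)) background <- unique(unlist(collection$sets))
  background <- unique(background)
  N <- length(background)
  sets <- lapply(collection$sets, intersect, background)
  if (any(lengths(sets) == 0))
    stop("background excludes every member of set(s): ",
         paste(utils::head(names(sets)[lengths(sets) == 0], 5),
               collapse = ", "))
  query <- unique(query)
  empty <- data.frame(mirna_id = character(), pathway_id = character(),
                      pathway_name = character(), overlap_count = integer(),
                      query_size = integer(), pathway_size = integer(),
                      background_size = integer(), p_value = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  empty$overlap_genes <- list()
  if (length(query) == 0) {
    warning("empty query gene set; no enrichment computed")
    return(empty)
  }
  outside <- setdiff(query, background)
  if (length(outside))
    stop("query gene(s) outside the background universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  n <- length(query)
  rows <- lapply(names(sets), function(id) {
    K <- length(sets[[id]])
    ov <- sort(intersect(query, sets[[id]]))
    k <- length(ov)
    if (k == 0) return(NULL)
    k_eff <- if (ease) k - 1L else k
    p <- stats::phyper(k_eff - 1, K, N - K, n, lower.tail = FALSE)
    r <- data.frame(mirna_id = mirna_id, pathway_id = id,
                    pathway_name = unname(collection$set_names[[id]]),
                    overlap_count = k, query_size = n, pathway_size = K,
                    background_size = N, p_value = p,
                    significant = p <= alpha, stringsAsFactors = FALSE)
    r$overlap_genes <- list(ov)
    r
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$pathway_id), ]
  rownames(out) <- NULL
  out
}

#' Per-miRNA pathway enrichment of candidate targets
#'
#' Runs [enrich()] once per miRNA on its candidate target genes and
#' stacks the results, mirroring the per-miRNA enrichment tables
#' reported for this kind of analysis.
#'
#' @param candidates data frame from [candidate_interactions()].
#' @param collection a [gene_set_collection()].
#' @inheritParams enrich
#' @return Stacked [enrich()] data frame across miRNAs.
#' @export
enrich_per_mirna <- function(candidates, collection, background = NULL,
                             alpha = 0.05, ease = FALSE) {
  mirnas <- sort(unique(candidates$mirna_id))
  out <- lapply(mirnas, function(m) {
    genes <- candidates$gene_id[candidates$mirna_id == m]
    if (is.null(background)) {
      bg <- collection$background
      if (is.null(bg)) bg <- unique(unlist(collection$sets))
      genes <- intersect(genes, bg)
    }
    if (length(genes) == 0) return(NULL)
    enrich(genes, collection, background = background, alpha = alpha,
           ease = ease, mirna_id = m)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(enrich(character(0), collection, background = background))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
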