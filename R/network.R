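#' Anti-correlated candidate miRNA-gene interactions
#'
#' MiRNAs predominantly repress their targets, so a predicted interaction
#' is plausible in expression data only when the miRNA and the gene move
#' in opposite directions: up-regulated miRNA with down-regulated target,
#' or down-regulated miRNA with up-regulated target. Same-direction pairs
#' are dropped.
#'
#' @param interactions data frame with columns `mirna_id`, `gene_id`,
#'   `mirna_direction`, `gene_direction` (from [restrict_to_de()] or
#'   [expand_summary_interactions()]).
#' @return The anti-correlated subset of `interactions`.
#' @export
candidate_interactions <- function(interactions) {
  needed <- c("mirna_id", "gene_id", "mirna_direction", "gene_direction")
  missing <- setdiff(needed, names(interactions))
  if (length(missing))
    stop("missing direction annotation column(s): ",
         paste(missing, collapse = ", "))
  if (any(is.na(interactions$mirna_direction)) ||
      any(is.na(interactions$gene_direction)))
    stop("interactions with missing direction annotations")
  keep <- interactions$mirna_direction != interactions$gene_direction
  out <- interactions[keep, needed, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a bipartite miRNA-gene regulatory network
#'
#' Nodes are typed (miRNA or gene) and carry their regulation direction;
#' edges run miRNA -> gene, one per candidate interaction. Each miRNA
#' node's `n_targets` attribute is its candidate-target count (the usual
#' node-size channel when the network is drawn). MiRNAs with zero
#' candidates never enter the node set.
#'
#' @param candidates data frame from [candidate_interactions()].
#' @return A `regulatory_network`: list with `nodes` (id, type,
#'   direction, n_targets), `edges` (from, relation, to,
#'   mirna_direction, gene_direction), both lexicographically ordered.
#' @export
build_network <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(structure(list(
      nodes = data.frame(id = character(), type = character(),
                         direction = character(), n_targets = integer(),
                         stringsAsFactors = FALSE),
      edges = data.frame(from = character(), relation = character(),
                         to = character(), mirna_direction = character(),
                         gene_direction = character(),
                         stringsAsFactors = FALSE)),
      class = "regulatory_network"))
  }
  key <- paste(candidates$mirna_id, candidates$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    candidates <- candidates[!duplicated(key), , drop = FALSE]
  }
  edges <- data.frame(from = candidates$mirna_id, relation = "represses",
                      to = candidates$gene_id,
                      mirna_direction = candidates$mirna_direction,
                      gene_direction = candidates$gene_direction,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL

  deg <- table(edges$from)
  mdir <- tapply(edges$mirna_direction, edges$from, `[[`, 1)
  gdir <- tapply(edges$gene_direction, edges$to, `[[`, 1)
  m_ids <- sort(unique(edges$from))
  g_ids <- sort(unique(edges$to))
  nodes <- rbind(
    data.frame(id = m_ids, type = "miRNA",
               direction = unname(mdir[m_ids]),
               n_targets = as.integer(deg[m_ids]),
               stringsAsFactors = FALSE),
    data.frame(id = g_ids, type = "gene",
               direction = unname(gdir[g_ids]),
               n_targets = NA_integer_, stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network: %d miRNAs, %d genes, %d edges\n",
              sum(x$nodes$type == "miRNA"), sum(x$nodes$type == "gene"),
              nrow(x$edges)))
  invisible(x)
}

#' Split a network into up- and down-miRNA subnetworks
#'
#' @param network a `regulatory_network`.
#' @return Named list of two `regulatory_network`s, `up` (up-regulated
#'   miRNAs, down-regulated targets) and `down`.
#' @export
split_by_mirna_direction <- function(network) {
  e <- network$edges
  mk <- function(dir) {
    build_network(data.frame(mirna_id = e$from, gene_id = e$to,
                             mirna_direction = e$mirna_direction,
                             gene_direction = e$gene_direction,
                             stringsAsFactors = FALSE)[e$mirna_direction == dir, ,
                                                       drop = FALSE])
  }
  list(up = mk("up"), down = mk("down"))
}

#' Novel out degree (NOD) per miRNA
#'
#' The NOD of a miRNA is the number of its target genes regulated by that
#' miRNA alone within the network -- genes whose only incoming edge comes
#' from it. It measures the independent regulatory power of each miRNA;
#' `NOD(m) <= degree(m)` always.
#'
#' @param network a `regulatory_network`.
#' @return Named integer vector, one entry per miRNA node.
#' @export
nod <- function(network) {
  e <- network$edges
  mirnas <- network$nodes$id[network$nodes$type == "miRNA"]
  if (nrow(e) == 0)
    return(stats::setNames(integer(length(mirnas)), mirnas))
  indeg <- table(e$to)
  unique_genes <- names(indeg)[indeg == 1]
  sole <- e[e$to %in% unique_genes, ]
  counts <- table(factor(sole$from, levels = mirnas))
  stats::setNames(as.integer(counts), mirnas)
}

#' Genes regulated by exactly one miRNA
#'
#' @param network a `regulatory_network`.
#' @return Character vector of gene ids with a single regulator.
#' @export
uniquely_regulated_genes <- function(network) {
  e <- network$edges
  if (nrow(e) == 0) return(character())
  indeg <- table(e$to)
  sort(names(indeg)[indeg == 1])
}

#' Connected components of a regulatory network
#'
#' The directed network is treated as undirected for connectivity.
#' Components are returned in decreasing size, ties broken by the
#' lexicographically smallest member node, members sorted within each.
#'
#' @param network a `regulatory_network`.
#' @return List of character vectors of node ids (possibly empty list).
#' @export
network_components <- function(network) {
  if (nrow(network$nodes) == 0) return(list())
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes$id)
  comp <- igraph::components(g)
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, sort)
  ord <- order(-lengths(parts), vapply(parts, `[[`, "", 1))
  unname(parts[ord])
}

#' Exact test for a 2x2 contingency table
#'
#' Conditions on both margins, so table probabilities are hypergeometric.
#' The one-sided (`"greater"`) p-value is the upper tail over the first
#' cell; the two-sided p-value sums the probabilities of all tables with
#' the observed margins whose point probability does not exceed the
#' observed table's (with a 1e-7 relative tolerance for ties).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise
#'   (`[[a, b], [c, d]]`).
#' @param alternative `"two.sided"` or `"greater"`.
#' @return The exact p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero contingency table")
  m <- a + b          # first row total
  n <- c + d          # second row total
  k <- a + c          # first column total
  lo <- max(0, k - n)
  hi <- min(k, m)
  support <- lo:hi
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  if (alternative == "greater")
    return(min(1, sum(exp(logp[support >= a]))))
  p_obs <- logp[support == a]
  min(1, sum(exp(logp[logp <= p_obs + log1p(1e-7)])))
}

#' Exclusivity of unique regulation between subnetworks
#'
#' One plausible formalization of whether uniquely regulated genes are
#' distributed differently between the up- and the down-miRNA
#' subnetworks: a 2x2 table of gene counts, unique vs shared regulation
#' by subnetwork, tested with [fisher_exact_2x2()]. The contingency
#' behind this kind of comparison can be framed in more than one way;
#' this helper documents one concrete, reproducible choice.
#'
#' @param network a `regulatory_network` containing both miRNA direction
#'   classes.
#' @return List with the 2x2 `table` (matrix) and the two-sided
#'   `p_value`.
#' @export
nod_exclusivity_test <- function(network) {
  sub <- split_by_mirna_direction(network)
  cnt <- function(nw) {
    genes <- nw$nodes$id[nw$nodes$type == "gene"]
    uniq <- uniquely_regulated_genes(nw)
    c(unique = length(uniq), shared = length(genes) - length(uniq))
  }
  up <- cnt(sub$up); down <- cnt(sub$down)
  tab <- rbind(up = up, down = down)
  p <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                        alternative = "two.sided")
  list(table = tab, p_value = p)
}

#' Assemble a tripartite miRNA-gene-pathway network
#'
#' Extends the bipartite network with pathway nodes and gene->pathway
#' membership edges, one per gene in an enriched pathway's overlap set.
#' Genes uniquely regulated by a single miRNA are flagged (the usual
#' red-asterisk annotation in drawn networks).
#'
#' @param network a `regulatory_network` built from the candidates.
#' @param enrichment data frame from [enrich()] (typically its
#'   significant rows), with `pathway_id`, `pathway_name` and an
#'   `overlap_genes` list column.
#' @return A `tripartite_network`: list with `nodes` (id, type,
#'   direction, unique_regulator flag) and `edges` (from, relation, to).
#' @export
assemble_tripartite <- function(network, enrichment) {
  genes <- network$nodes$id[network$nodes$type == "gene"]
  base_edges <- network$edges[, c("from", "relation", "to")]
  if (nrow(enrichment) > 0) {
    overlap <- enrichment$overlap_genes
    dangling <- setdiff(unique(unlist(overlap)), genes)
    if (length(dangling))
      stop("enrichment references gene(s) absent from the network: ",
           paste(utils::head(dangling, 5), collapse = ", "))
    pw_edges <- do.call(rbind, lapply(seq_len(nrow(enrichment)), function(i)
      data.frame(from = sort(overlap[[i]]), relation = "member_of",
                 to = enrichment$pathway_id[i], stringsAsFactors = FALSE)))
    pw_edges <- unique(pw_edges)
    pw_nodes <- unique(data.frame(id = enrichment$pathway_id,
                                  type = "pathway", direction = NA_character_,
                                  stringsAsFactors = FALSE))
  } else {
    pw_edges <- base_edges[0, ]
    pw_nodes <- data.frame(id = character(), type = character(),
                           direction = character(), stringsAsFactors = FALSE)
  }
  uniq <- uniquely_regulated_genes(network)
  nodes <- rbind(network$nodes[, c("id", "type", "direction")], pw_nodes)
  nodes$unique_regulator <- nodes$type == "gene" & nodes$id %in% uniq
  nodes <- nodes[order(nodes$type, nodes$id), ]
  rownames(nodes) <- NULL
  edges <- rbind(base_edges, pw_edges)
  edges <- edges[order(edges$relation, edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = c("tripartite_network", "regulatory_network"))
}

#' Per-miRNA interaction summary table
#'
#' One row per consistently differentially expressed miRNA: its
#' direction, total consensus-predicted targets, differentially
#' expressed targets split by gene direction, and anti-correlated
#' candidate targets (always the direction-opposed column). MiRNAs
#' without any DE target keep a row of zeros.
#'
#' @param de_mirnas `consistent_sets` for miRNAs.
#' @param consensus data frame of consensus interactions (`mirna_id`,
#'   `gene_id`) before DE restriction.
#' @param restricted data frame from [restrict_to_de()].
#' @param candidates data frame from [candidate_interactions()].
#' @return Data frame matching the shape of [hcsc_target_summary()].
#' @export
summarize_interaction_table <- function(de_mirnas, consensus, restricted,
                                        candidates) {
  stopifnot(inherits(de_mirnas, "consistent_sets"))
  mirnas <- c(de_mirnas$up, de_mirnas$down)
  dirs <- rep(c("up", "down"),
              c(length(de_mirnas$up), length(de_mirnas$down)))
  cnt <- function(df, mirna, ...) {
    keep <- df$mirna_id == mirna
    extra <- list(...)
    if (length(extra))
      keep <- keep & df$gene_direction == extra[[1]]
    sum(keep)
  }
  out <- data.frame(
    mirna_id = mirnas, direction = dirs,
    total_predicted = vapply(mirnas, function(m) cnt(consensus, m), 0L),
    de_targets = vapply(mirnas, function(m) cnt(restricted, m), 0L),
    up_de_targets = vapply(mirnas, function(m) cnt(restricted, m, "up"), 0L),
    down_de_targets = vapply(mirnas, function(m)
      cnt(restricted, m, "down"), 0L),
    candidate_targets = vapply(mirnas, function(m) cnt(candidates, m), 0L),
    stringsAsFactors = FALSE)
  out <- out[order(match(out$direction, c("down", "up")), out$mirna_id), ]
  rownames(out) <- NULL
  out
}
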