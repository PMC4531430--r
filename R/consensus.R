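#' Consensus miRNA-target interactions
#'
#' Retains predicted (miRNA, gene) pairs supported by at least
#' `min_sources` independent prediction sources. Raising `min_sources`
#' can only shrink the retained set.
#'
#' @param evidence merged evidence from [merge_evidence()].
#' @param min_sources minimum number of supporting sources (default 2).
#' @return The subset of `evidence` rows with `n_sources >= min_sources`.
#' @export
consensus_interactions <- function(evidence, min_sources = 2L) {
  if (min_sources < 1) stop("min_sources must be at least 1")
  out <- evidence[evidence$n_sources >= min_sources, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict interactions to differentially expressed miRNAs and genes
#'
#' Keeps interactions whose miRNA is consistently differentially expressed
#' (up or down) and whose gene is as well, annotating each side's
#' direction. This is the step that places differential gene expression in
#' the context of predicted miRNA-mRNA interactions.
#'
#' @param interactions data frame with `mirna_id`, `gene_id` columns
#'   (e.g. from [consensus_interactions()]).
#' @param de_mirnas,de_genes `consistent_sets` objects (see
#'   [consistent_features()]).
#' @return Data frame with columns `mirna_id`, `gene_id`,
#'   `mirna_direction`, `gene_direction`; possibly zero rows.
#' @export
restrict_to_de <- function(interactions, de_mirnas, de_genes) {
  stopifnot(inherits(de_mirnas, "consistent_sets"),
            inherits(de_genes, "consistent_sets"))
  mdir <- c(stats::setNames(rep("up", length(de_mirnas$up)), de_mirnas$up),
            stats::setNames(rep("down", length(de_mirnas$down)),
                            de_mirnas$down))
  gdir <- c(stats::setNames(rep("up", length(de_genes$up)), de_genes$up),
            stats::setNames(rep("down", length(de_genes$down)),
                            de_genes$down))
  keep <- interactions$mirna_id %in% names(mdir) &
          interactions$gene_id %in% names(gdir)
  out <- data.frame(mirna_id = interactions$mirna_id[keep],
                    gene_id = interactions$gene_id[keep],
                    stringsAsFactors = FALSE)
  out$mirna_direction <- unname(mdir[out$mirna_id])
  out$gene_direction <- unname(gdir[out$gene_id])
  rownames(out) <- NULL
  out
}

#' Reference per-miRNA target summary fixture
#'
#' Loads the packaged summary of predicted and differentially expressed
#' target genes for the 18 consistently differentially expressed miRNAs
#' found in the hepatic cancer stem-cell study system (Hep3B/Huh7
#' stem-enriched vs parental lines): per miRNA, its regulation direction,
#' total consensus-predicted targets, differentially expressed targets
#' split by direction, and anti-correlated candidate targets. Row
#' arithmetic satisfies `de_targets = up_de_targets + down_de_targets`
#' and `candidate_targets` equals the direction-opposed column.
#'
#' @return Data frame with columns `mirna_id`, `direction`,
#'   `total_predicted`, `de_targets`, `up_de_targets`, `down_de_targets`,
#'   `candidate_targets`.
#' @export
hcsc_target_summary <- function() {
  path <- system.file("extdata", "hcsc_mirna_target_summary.tsv",
                      package = "mirgnet", mustWork = TRUE)
  tab <- read_tsv_strict(path, c("mirna_id", "direction", "total_predicted",
                                 "de_targets", "up_de_targets",
                                 "down_de_targets", "candidate_targets"))
  stopifnot(all(tab$de_targets == tab$up_de_targets + tab$down_de_targets))
  tab
}

#' Expand a per-miRNA target summary into annotated interactions
#'
#' Reconstructs an interaction table compatible with
#' [candidate_interactions()] from aggregate per-miRNA counts, inventing
#' placeholder gene ids (one per counted target, unique per miRNA). Gene
#' identity across miRNAs is not preserved -- the expansion supports
#' interaction counting, not distinct-gene statistics.
#'
#' @param summary data frame in the shape of [hcsc_target_summary()].
#' @return Data frame with columns `mirna_id`, `gene_id`,
#'   `mirna_direction`, `gene_direction`.
#' @export
expand_summary_interactions <- function(summary) {
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    r <- summary[i, ]
    n_up <- r$up_de_targets
    n_dn <- r$down_de_targets
    if (n_up + n_dn == 0)
      return(NULL)
    data.frame(
      mirna_id = r$mirna_id,
      gene_id = paste0(r$mirna_id, ":target",
                       seq_len(n_up + n_dn)),
      mirna_direction = r$direction,
      gene_direction = rep(c("up", "down"), c(n_up, n_dn)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
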