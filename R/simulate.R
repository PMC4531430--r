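# Seeded synthetic-data generator. Emulates the structure of the study
# system: two stem/parental cell-line pairs, deep tag counts for miRNAs
# (library scale 1e7) and genes (1e6), planted differential expression
# with anti-correlated miRNA targeting, multiple noisy target-prediction
# sources, and pathway collections with an optional planted enrichment.
# Every generator is a pure function of (config, seed).

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: two cell-line pairs;
#' sequencing depth 1e7 (miRNA tags) and 1e6 (genes); 5% of features
#' differentially expressed with log2 effect 2 (4-fold) of random sign,
#' concordant across both pairs; Poisson count noise (negative binomial
#' available to stress robustness); null abundances log-uniform on
#' 30-3000 tags/reads per million, the typical range of features
#' retained after low-abundance filtering; 7 prediction sources with
#' per-pair sensitivity 0.8 and false-positive rate 1e-4; ~300 targets
#' per miRNA with targets of a differentially expressed miRNA biased
#' (weight 10) toward oppositely regulated genes, so anti-correlated
#' candidate sets of realistic size arise; 40 pathways of 30-120 genes
#' with planted enrichment factor 5.
#'
#' @param seed mandatory integer seed; every derived dataset is a pure
#'   function of the config including its seed.
#' @param n_genes,n_mirnas feature counts per class.
#' @param depth_genes,depth_mirnas per-sample library sizes (total
#'   mapped reads).
#' @param de_fraction fraction of features per class that are truly
#'   differentially expressed.
#' @param effect_log2 absolute log2 fold change of true effects.
#' @param noise `"poisson"` or `"nb"`.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`) when `noise = "nb"`.
#' @param concordance probability a true effect is present in both
#'   cell-line pairs (otherwise in one pair only).
#' @param lambda_range log-uniform range of null feature abundance, per
#'   million.
#' @param gene_length_range uniform range of gene lengths (nt).
#' @param n_sources,source_sensitivity,source_fp_rate prediction-source
#'   count, per-true-pair detection probability, and per-false-pair
#'   inclusion probability.
#' @param max_source_rows cap on the expected row count of one simulated
#'   source file.
#' @param targets_per_mirna true targets drawn per miRNA.
#' @param target_de_bias sampling weight multiplier pulling a DE miRNA's
#'   targets toward oppositely regulated DE genes.
#' @param n_pathways,set_size_range pathway collection shape.
#' @param planting_factor multiplier on the inclusion rate of the chosen
#'   miRNA's candidate target genes in the planted pathway; 1 disables
#'   planting.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 2000L, n_mirnas = 300L,
                       depth_genes = 1e6, depth_mirnas = 1e7,
                       de_fraction = 0.05, effect_log2 = 2,
                       noise = c("poisson", "nb"), dispersion = 0.1,
                       concordance = 1.0,
                       lambda_range = c(30, 3000),
                       gene_length_range = c(500, 5000),
                       n_sources = 7L, source_sensitivity = 0.8,
                       source_fp_rate = 1e-4, max_source_rows = 1e6,
                       targets_per_mirna = 300L, target_de_bias = 10,
                       n_pathways = 40L, set_size_range = c(30L, 120L),
                       planting_factor = 5) {
  noise <- match.arg(noise)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(seed == round(seed), n_genes > 0, n_mirnas > 0,
            depth_genes > 0, depth_mirnas > 0,
            de_fraction >= 0, de_fraction <= 1,
            concordance >= 0, concordance <= 1,
            source_sensitivity >= 0, source_sensitivity <= 1,
            source_fp_rate >= 0, source_fp_rate <= 1,
            n_sources >= 1, targets_per_mirna >= 1, target_de_bias >= 1,
            planting_factor >= 1, effect_log2 > 0, dispersion > 0,
            all(lambda_range > 0), diff(lambda_range) >= 0)
  structure(as.list(environment()), class = "sim_config")
}

draw_counts <- function(mu, noise, dispersion) {
  if (noise == "poisson") stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

simulate_class <- function(ids, depth, config) {
  n <- length(ids)
  lambda <- exp(stats::runif(n, log(config$lambda_range[1]),
                             log(config$lambda_range[2])))
  n_de <- round(config$de_fraction * n)
  de_idx <- sample(n, n_de)
  sign <- sample(c(1, -1), n_de, replace = TRUE)
  in_both <- stats::runif(n_de) < config$concordance
  which_pair <- sample(1:2, n_de, replace = TRUE)
  pair_names <- c("cellline1", "cellline2")

  effect <- matrix(0, n, 2)  # log2 effect per feature per pair
  for (j in 1:2) {
    active <- in_both | which_pair == j
    effect[de_idx[active], j] <- sign[active] * config$effect_log2
  }

  counts <- matrix(0, n, 4,
                   dimnames = list(ids, c("cellline1_stem", "cellline1_cancer",
                                          "cellline2_stem", "cellline2_cancer")))
  for (j in 1:2) {
    mu_cond <- lambda * 2^effect[, j] * depth / 1e6
    mu_ref <- lambda * depth / 1e6
    counts[, 2 * j - 1] <- draw_counts(mu_cond, config$noise,
                                       config$dispersion)
    counts[, 2 * j] <- draw_counts(mu_ref, config$noise, config$dispersion)
  }

  per_pair <- lapply(1:2, function(j) {
    list(up = sort(ids[effect[, j] > 0]), down = sort(ids[effect[, j] < 0]))
  })
  names(per_pair) <- pair_names
  consistent <- structure(
    list(up = sort(ids[effect[, 1] > 0 & effect[, 2] > 0]),
         down = sort(ids[effect[, 1] < 0 & effect[, 2] < 0])),
    class = "consistent_sets")
  list(counts = counts, per_pair = per_pair, consistent = consistent)
}

#' Simulate paired count tables with known ground truth
#'
#' Generates miRNA and gene count tables for two stem/parental cell-line
#' pairs, plus the true miRNA target map. Targets of a consistently
#' differentially expressed miRNA are sampled with extra weight on genes
#' consistently regulated in the opposite direction, emulating
#' miRNA-mediated repression; true anti-correlated candidate pairs are
#' recorded in the returned truth.
#'
#' @param config a [sim_config()].
#' @return List with `mirna_table`, `gene_table` ([count_table()]s),
#'   `pairing` ([sample_pairing()]), and `truth` (per-pair and consistent
#'   DE sets per class, `targets`, `candidates`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    gene_ids <- sprintf("gene%04d", seq_len(config$n_genes))
    mirna_ids <- sprintf("mir%03d", seq_len(config$n_mirnas))

    g <- simulate_class(gene_ids, config$depth_genes, config)
    m <- simulate_class(mirna_ids, config$depth_mirnas, config)
    lengths_ <- stats::setNames(
      round(stats::runif(config$n_genes, config$gene_length_range[1],
                         config$gene_length_range[2])), gene_ids)

    gene_table <- count_table(
      g$counts, feature_class = "gene",
      library_sizes = stats::setNames(rep(config$depth_genes, 4),
                                      colnames(g$counts)),
      feature_lengths = lengths_)
    mirna_table <- count_table(
      m$counts, feature_class = "miRNA",
      library_sizes = stats::setNames(rep(config$depth_mirnas, 4),
                                      colnames(m$counts)))
    pairing <- sample_pairing(data.frame(
      pair_id = c("cellline1", "cellline2"),
      condition_sample = c("cellline1_stem", "cellline2_stem"),
      reference_sample = c("cellline1_cancer", "cellline2_cancer"),
      stringsAsFactors = FALSE))

    gdir <- c(stats::setNames(rep("up", length(g$consistent$up)),
                              g$consistent$up),
              stats::setNames(rep("down", length(g$consistent$down)),
                              g$consistent$down))
    k <- min(config$targets_per_mirna, config$n_genes)
    targets <- do.call(rbind, lapply(mirna_ids, function(mid) {
      mdir <- if (mid %in% m$consistent$up) "up"
              else if (mid %in% m$consistent$down) "down" else NA
      w <- rep(1, config$n_genes)
      if (!is.na(mdir)) {
        opposite <- if (mdir == "up") "down" else "up"
        w[gene_ids %in% names(gdir)[gdir == opposite]] <- config$target_de_bias
      }
      data.frame(mirna_id = mid, gene_id = sort(sample(gene_ids, k, prob = w)),
                 stringsAsFactors = FALSE)
    }))
    rownames(targets) <- NULL

    mdir <- c(stats::setNames(rep("up", length(m$consistent$up)),
                              m$consistent$up),
              stats::setNames(rep("down", length(m$consistent$down)),
                              m$consistent$down))
    cand <- targets[targets$mirna_id %in% names(mdir) &
                    targets$gene_id %in% names(gdir), , drop = FALSE]
    if (nrow(cand)) {
      cand$mirna_direction <- unname(mdir[cand$mirna_id])
      cand$gene_direction <- unname(gdir[cand$gene_id])
      cand <- cand[cand$mirna_direction != cand$gene_direction, ,
                   drop = FALSE]
    } else {
      cand$mirna_direction <- character(0)
      cand$gene_direction <- character(0)
    }
    rownames(cand) <- NULL

    list(mirna_table = mirna_table, gene_table = gene_table,
         pairing = pairing,
         truth = list(gene = c(g$per_pair, list(consistent = g$consistent)),
                      mirna = c(m$per_pair, list(consistent = m$consistent)),
                      gene_ids = gene_ids, mirna_ids = mirna_ids,
                      targets = targets, candidates = cand))
  })
}

#' Simulate noisy target-prediction sources
#'
#' Each source includes every true (miRNA, gene) pair independently with
#' probability `source_sensitivity`, and every non-target pair with
#' probability `source_fp_rate` (false pairs drawn uniformly from the
#' complement). Sources are conditionally independent given the truth.
#'
#' @param truth truth list from [simulate_counts()] (uses `targets`,
#'   `gene_ids`, `mirna_ids`).
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, each source is written
#'   as `source<k>.tsv`.
#' @return Named list of per-source evidence data frames (`mirna_id`,
#'   `gene_id`, `source`), as returned by [read_prediction_source()].
#' @export
simulate_prediction_sources <- function(truth, config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth$targets) == 0) stop("truth target map is empty")
  n_total <- length(truth$mirna_ids) * length(truth$gene_ids)
  n_true <- nrow(truth$targets)
  expected <- n_true * config$source_sensitivity +
    (n_total - n_true) * config$source_fp_rate
  if (expected > config$max_source_rows)
    stop("source_fp_rate implies ~", round(expected),
         " rows per source, above the configured cap")

  gi <- match(truth$targets$gene_id, truth$gene_ids)
  mi <- match(truth$targets$mirna_id, truth$mirna_ids)
  true_idx <- (mi - 1) * length(truth$gene_ids) + gi
  false_idx <- setdiff(seq_len(n_total), true_idx)

  with_seed(config$seed + 1L, {
    sources <- lapply(seq_len(config$n_sources), function(s) {
      keep <- stats::runif(n_true) < config$source_sensitivity
      n_fp <- stats::rbinom(1, length(false_idx), config$source_fp_rate)
      fp <- if (n_fp > 0) sample(false_idx, n_fp) else integer()
      idx <- c(true_idx[keep], fp)
      mirna <- truth$mirna_ids[(idx - 1) %/% length(truth$gene_ids) + 1]
      gene <- truth$gene_ids[(idx - 1) %% length(truth$gene_ids) + 1]
      out <- data.frame(mirna_id = mirna, gene_id = gene,
                        source = rep(sprintf("source%d", s), length(idx)),
                        stringsAsFactors = FALSE)
      out <- out[order(out$mirna_id, out$gene_id), ]
      rownames(out) <- NULL
      out
    })
    names(sources) <- sprintf("source%d", seq_len(config$n_sources))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in names(sources))
        utils::write.table(sources[[nm]][, c("mirna_id", "gene_id")],
                           file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    sources
  })
}

#' Simulate a pathway collection with an optional planted enrichment
#'
#' Background pathways are uniform draws from the gene universe. When
#' `planting_factor > 1`, the first pathway over-samples the true
#' anti-correlated candidate targets of a chosen miRNA: each such gene
#' enters the planted set with probability
#' `min(1, planting_factor * K / N)` instead of the base rate `K / N`.
#'
#' @param truth truth list from [simulate_counts()].
#' @param config a [sim_config()].
#' @param planted_mirna miRNA whose candidate targets are planted;
#'   default is the miRNA with the most true candidates.
#' @return List with `collection` (a [gene_set_collection()] whose
#'   background is the full gene universe), `planted_pathway` (id or
#'   `NA`), `planted_mirna`.
#' @export
simulate_gene_sets <- function(truth, config, planted_mirna = NULL) {
  stopifnot(inherits(config, "sim_config"))
  universe <- truth$gene_ids
  N <- length(universe)
  if (max(config$set_size_range) > N)
    stop("pathway set size exceeds the gene universe")
  plant <- config$planting_factor > 1 && nrow(truth$candidates) > 0
  if (plant && is.null(planted_mirna)) {
    tab <- sort(table(truth$candidates$mirna_id), decreasing = TRUE)
    planted_mirna <- names(tab)[1]
  }
  with_seed(config$seed + 2L, {
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_pathways, replace = TRUE)
    ids <- sprintf("pathway%02d", seq_len(config$n_pathways))
    sets <- vector("list", config$n_pathways)
    for (i in seq_len(config$n_pathways)) {
      if (plant && i == 1) {
        cand <- truth$candidates$gene_id[
          truth$candidates$mirna_id == planted_mirna]
        rate <- min(1, config$planting_factor * sizes[i] / N)
        inside <- cand[stats::runif(length(cand)) < rate]
        if (length(inside) > sizes[i]) inside <- inside[seq_len(sizes[i])]
        rest <- sample(setdiff(universe, inside),
                       sizes[i] - length(inside))
        sets[[i]] <- sort(c(inside, rest))
      } else {
        sets[[i]] <- sort(sample(universe, sizes[i]))
      }
    }
    names(sets) <- ids
    list(collection = gene_set_collection(sets, background = universe),
         planted_pathway = if (plant) ids[1] else NA_character_,
         planted_mirna = if (plant) planted_mirna else NA_character_)
  })
}

#' Simulate a complete study
#'
#' Runs [simulate_counts()], [simulate_prediction_sources()] and
#' [simulate_gene_sets()] under one config; optionally writes every
#' input format plus a `truth.json` snapshot to a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return List with `counts` (list from [simulate_counts()]),
#'   `sources`, `gene_sets`.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  counts <- simulate_counts(config)
  sources <- simulate_prediction_sources(
    counts$truth, config,
    out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "sources"))
  gene_sets <- simulate_gene_sets(counts$truth, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_count_table(counts$mirna_table,
                      file.path(out_dir, "mirna_counts.tsv"))
    write_count_table(counts$gene_table,
                      file.path(out_dir, "gene_counts.tsv"))
    write_gmt(gene_sets$collection, file.path(out_dir, "pathways.gmt"))
    truth_out <- counts$truth
    truth_out$targets <- NULL; truth_out$candidates <- NULL
    truth_out$planted_pathway <- gene_sets$planted_pathway
    truth_out$planted_mirna <- gene_sets$planted_mirna
    jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    utils::write.table(counts$truth$targets,
                       file.path(out_dir, "true_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(counts = counts, sources = sources, gene_sets = gene_sets)
}
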