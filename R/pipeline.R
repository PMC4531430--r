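#' Run the full regulatory-network analysis
#'
#' Orchestrates the stages in fixed order: read/validate inputs,
#' normalize, call differential expression per pair, intersect consistent
#' features across pairs, merge prediction evidence, apply the consensus
#' and differential-expression restrictions, keep anti-correlated
#' candidates, build the bipartite network with NOD and component
#' statistics, run per-miRNA pathway enrichment, assemble the tripartite
#' network, and write all outputs plus a JSON run manifest. Any stage
#' failure aborts with the stage name; outputs are deterministic given
#' inputs and config.
#'
#' @param config configuration list, or path to a YAML file with the
#'   same shape. Recognized entries: `mirna_counts`, `gene_counts`
#'   (count TSV paths), `pairs` (data frame or list with
#'   `condition_sample`/`reference_sample`), `sources` (named list of
#'   prediction TSV paths, or a directory), `gmt` (GMT path),
#'   `library_sizes` (named list per class, or `"column-sum"`),
#'   `thresholds` (arguments to [threshold_config()]), `ease`,
#'   `enrichment_background`.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  thresholds <- do.call(threshold_config,
                        as.list(config$thresholds %||% list()))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, stages = list(),
                   version = as.character(utils::packageVersion("mirgnet")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  note <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message(sprintf("[%s] %s", name,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  lib_sizes <- function(class_) {
    ls <- config$library_sizes[[class_]]
    if (is.null(ls)) "column-sum" else unlist(ls)
  }
  inputs <- stage("read_inputs", {
    for (p in c(config$mirna_counts, config$gene_counts, config$gmt))
      if (!file.exists(p)) stop("missing input file: ", p)
    mirna <- read_count_table(config$mirna_counts, "miRNA",
                              library_sizes = lib_sizes("mirna"))
    gene <- read_count_table(config$gene_counts, "gene",
                             library_sizes = lib_sizes("gene"))
    if (length(mirna$feature_ids) == 0 || length(gene$feature_ids) == 0)
      stop("empty count table")
    src_spec <- config$sources
    if (is.character(src_spec) && length(src_spec) == 1 &&
        dir.exists(src_spec)) {
      files <- list.files(src_spec, pattern = "\\.tsv$", full.names = TRUE)
      src_spec <- stats::setNames(as.list(files),
                                  tools::file_path_sans_ext(basename(files)))
    }
    sources <- lapply(names(src_spec), function(nm)
      read_prediction_source(src_spec[[nm]], nm))
    collection <- read_gmt(config$gmt)
    pairing <- sample_pairing(as.data.frame(
      do.call(rbind, lapply(config$pairs, as.data.frame))))
    list(mirna = mirna, gene = gene, sources = sources,
         collection = collection, pairing = pairing)
  })
  note("read_inputs", mirnas = length(inputs$mirna$feature_ids),
       genes = length(inputs$gene$feature_ids),
       sources = length(inputs$sources),
       pathways = length(inputs$collection$sets))

  run_pipeline_stages(inputs$mirna, inputs$gene, inputs$pairing,
                      inputs$sources, inputs$collection, thresholds,
                      out_dir, manifest, note = NULL,
                      ease = isTRUE(config$ease),
                      background = config$enrichment_background)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis stages on in-memory objects
#'
#' The computational core of [run_pipeline()], callable directly on
#' objects (as produced by [simulate_study()]) without touching disk for
#' the inputs.
#'
#' @param mirna_table,gene_table [count_table()]s.
#' @param pairing a [sample_pairing()] with exactly two pairs.
#' @param sources list of per-source evidence data frames.
#' @param collection a [gene_set_collection()].
#' @param thresholds a [threshold_config()].
#' @param out_dir optional output directory; when `NULL` nothing is
#'   written.
#' @param manifest,note internal (used by [run_pipeline()]).
#' @param ease use the EASE enrichment variant.
#' @param background optional explicit enrichment universe.
#' @return Invisibly, a list with `de`, `consistent`, `evidence`,
#'   `consensus`, `restricted`, `candidates`, `network`, `subnetworks`,
#'   `nod`, `components`, `summary`, `enrichment`, `tripartite`,
#'   `manifest`.
#' @export
run_pipeline_stages <- function(mirna_table, gene_table, pairing, sources,
                                collection, thresholds = threshold_config(),
                                out_dir = NULL, manifest = NULL, note = NULL,
                                ease = FALSE, background = NULL) {
  if (is.null(manifest)) manifest <- list(stages = list())
  if (is.null(note))
    note <- function(name, ...) {
      manifest$stages[[name]] <<- list(...)
      message(sprintf("[%s] %s", name,
                      paste(names(list(...)), unlist(list(...)),
                            sep = "=", collapse = " ")))
    }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (nrow(pairing$pairs) != 2)
    stop("the consistency intersection needs exactly two sample pairs")

  de <- stage("diffexpr", {
    list(mirna = call_de_pairs(mirna_table, pairing, thresholds),
         gene = call_de_pairs(gene_table, pairing, thresholds))
  })
  p1 <- pairing$pairs$pair_id[1]; p2 <- pairing$pairs$pair_id[2]
  consistent <- stage("consistent", {
    list(mirna = consistent_features(de$mirna[de$mirna$pair_id == p1, ],
                                     de$mirna[de$mirna$pair_id == p2, ]),
         gene = consistent_features(de$gene[de$gene$pair_id == p1, ],
                                    de$gene[de$gene$pair_id == p2, ]))
  })
  note("diffexpr",
       de_mirna_up = length(consistent$mirna$up),
       de_mirna_down = length(consistent$mirna$down),
       de_gene_up = length(consistent$gene$up),
       de_gene_down = length(consistent$gene$down))

  evidence <- stage("merge_evidence", merge_evidence(sources))
  consensus <- stage("consensus",
                     consensus_interactions(evidence,
                                            thresholds$min_sources))
  restricted <- stage("restrict_to_de",
                      restrict_to_de(consensus, consistent$mirna,
                                     consistent$gene))
  candidates <- stage("candidates", candidate_interactions(restricted))
  note("interactions", evidence = nrow(evidence),
       consensus = nrow(consensus), de_restricted = nrow(restricted),
       candidates = nrow(candidates))

  network <- stage("network", build_network(candidates))
  subnets <- stage("subnetworks", split_by_mirna_direction(network))
  nod_values <- stage("nod", nod(network))
  components <- stage("components", network_components(network))
  summary_tab <- stage("summary",
                       summarize_interaction_table(consistent$mirna,
                                                   consensus, restricted,
                                                   candidates))
  note("network", nodes = nrow(network$nodes), edges = nrow(network$edges),
       components = length(components))

  enrichment <- stage("enrichment",
                      enrich_per_mirna(candidates, collection,
                                       background = background,
                                       alpha = thresholds$enrichment_alpha,
                                       ease = ease))
  tripartite <- stage("tripartite",
                      assemble_tripartite(
                        network,
                        enrichment[enrichment$significant, , drop = FALSE]))
  note("enrichment", tested = nrow(enrichment),
       significant = sum(enrichment$significant))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cls in c("mirna", "gene"))
      write_results_table(de[[cls]],
                          file.path(out_dir, paste0("de_", cls, ".tsv")))
    write_network(network, file.path(out_dir, "network.sif"), "sif")
    write_results_table(
      data.frame(mirna = network$edges$from, gene = network$edges$to,
                 mirna_dir = network$edges$mirna_direction,
                 gene_dir = network$edges$gene_direction),
      file.path(out_dir, "edges.tsv"))
    write_results_table(
      data.frame(mirna_id = names(nod_values), nod = unname(nod_values)),
      file.path(out_dir, "nod.tsv"))
    write_results_table(summary_tab,
                        file.path(out_dir, "summary_table.tsv"))
    write_results_table(enrichment, file.path(out_dir, "enrichment.tsv"))
    write_network(tripartite, file.path(out_dir, "tripartite.sif"), "sif")
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  invisible(list(de = de, consistent = consistent, evidence = evidence,
                 consensus = consensus, restricted = restricted,
                 candidates = candidates, network = network,
                 subnetworks = subnets, nod = nod_values,
                 components = components, summary = summary_tab,
                 enrichment = enrichment, tripartite = tripartite,
                 manifest = manifest))
}
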