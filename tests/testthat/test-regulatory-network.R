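test_that("anti-correlation filter keeps exactly opposite-direction pairs", {
  s <- hcsc_target_summary()
  cand <- candidate_interactions(expand_summary_interactions(s))
  per <- table(factor(cand$mirna_id, levels = s$mirna_id))
  expect_equal(unname(per[["hsa-miR-338-5p"]]), 141)
  expect_equal(unname(per[["hsa-miR-450b-5p"]]), 138)
  # a down-miRNA with only down-DE targets yields zero candidates
  only_down <- data.frame(mirna_id = "m", gene_id = c("g1", "g2"),
                          mirna_direction = "down", gene_direction = "down",
                          stringsAsFactors = FALSE)
  expect_equal(nrow(candidate_interactions(only_down)), 0)
  expect_error(candidate_interactions(only_down[, 1:2]), "direction")
})

test_that("anti-correlation filter equals a brute-force scan on random input", {
  withr::local_seed(71)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    ints <- data.frame(mirna_id = sample(sprintf("m%02d", 1:8), n, TRUE),
                       gene_id = sample(sprintf("g%03d", 1:80), n, TRUE),
                       mirna_direction = sample(c("up", "down"), n, TRUE),
                       gene_direction = sample(c("up", "down"), n, TRUE),
                       stringsAsFactors = FALSE)
    cand <- candidate_interactions(ints)
    brute <- sum(mapply(function(a, b) a != b,
                        ints$mirna_direction, ints$gene_direction))
    expect_equal(nrow(cand), brute)
  }
})

test_that("network construction conserves nodes and edges", {
  expect_equal(nrow(build_network(
    candidate_interactions(data.frame(
      mirna_id = character(), gene_id = character(),
      mirna_direction = character(), gene_direction = character())))$nodes),
    0)
  cand <- data.frame(mirna_id = "mA", gene_id = c("g1", "g2", "g3"),
                     mirna_direction = "up", gene_direction = "down",
                     stringsAsFactors = FALSE)
  net <- build_network(cand)
  expect_equal(nrow(net$nodes), 4)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$nodes$n_targets[net$nodes$id == "mA"], 3L)

  s <- hcsc_target_summary()
  net2 <- build_network(candidate_interactions(expand_summary_interactions(s)))
  sub <- split_by_mirna_direction(net2)
  expect_equal(nrow(sub$up$edges), 651)
  expect_equal(nrow(sub$down$edges), 103)
  # miRNAs with zero candidates (miR-378d, miR-1269b) never become nodes
  expect_false(any(c("hsa-miR-378d", "hsa-miR-1269b") %in% net2$nodes$id))
  expect_equal(sum(sub$up$nodes$type == "miRNA"), 7)
  expect_equal(sum(sub$down$nodes$type == "miRNA"), 9)
})

test_that("NOD counts genes with a single regulator", {
  # star: one miRNA, k genes -> NOD = k
  star <- build_network(data.frame(
    mirna_id = "mA", gene_id = sprintf("g%d", 1:5),
    mirna_direction = "up", gene_direction = "down"))
  expect_equal(nod(star), c(mA = 5L))
  expect_equal(uniquely_regulated_genes(star), sprintf("g%d", 1:5))
  # every gene shared by two miRNAs -> all NOD zero
  shared <- build_network(data.frame(
    mirna_id = rep(c("mA", "mB"), each = 3),
    gene_id = rep(sprintf("g%d", 1:3), 2),
    mirna_direction = "up", gene_direction = "down"))
  expect_equal(unname(nod(shared)), c(0L, 0L))
})

test_that("NOD and components match oracles on random bipartite graphs", {
  withr::local_seed(81)
  for (i in 1:60) {
    edges <- random_bipartite(sample(2:8, 1), sample(3:25, 1),
                              runif(1, 0.02, 0.3))
    if (nrow(edges) == 0) next
    edges$mirna_direction <- "up"
    edges$gene_direction <- "down"
    net <- build_network(edges)
    got <- nod(net)
    want <- oracle_nod(names(got), edges)
    expect_equal(unname(got), unname(want[names(got)]),
                 ignore_attr = TRUE)
    expect_true(all(got <= table(edges$mirna_id)[names(got)]))
    comps <- network_components(net)
    expect_equal(length(comps),
                 oracle_component_count(net$nodes$id, net$edges$from,
                                        net$edges$to))
    expect_setequal(unlist(comps), net$nodes$id)
    expect_true(all(diff(lengths(comps)) <= 0))
  }
})

test_that("component enumeration handles empty and disjoint networks", {
  empty <- build_network(data.frame(
    mirna_id = character(), gene_id = character(),
    mirna_direction = character(), gene_direction = character()))
  expect_identical(network_components(empty), list())
  two_stars <- build_network(data.frame(
    mirna_id = rep(c("mA", "mB"), each = 2),
    gene_id = c("g1", "g2", "g3", "g4"),
    mirna_direction = "up", gene_direction = "down"))
  expect_length(network_components(two_stars), 2)
})

test_that("exact 2x2 test reproduces enumerable cases", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
  # one-sided equals the hypergeometric upper-tail summation
  withr::local_seed(91)
  for (i in 1:100) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    ks <- max(0, K + n - N):min(K, n)
    k <- ks[sample.int(length(ks), 1)]
    expect_equal(fisher_exact_2x2(k, K - k, n - k, N - K - n + k,
                                  alternative = "greater"),
                 oracle_hyper_upper(k, n, K, N), tolerance = 1e-12)
  }
})

test_that("exact 2x2 test agrees with the reference implementation", {
  withr::local_seed(92)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(2, 5, 15), 1))
    if (sum(cells) == 0) next
    tab <- matrix(cells, 2, byrow = TRUE)
    for (alt in c("two.sided", "greater")) {
      expect_equal(
        fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4], alt),
        stats::fisher.test(tab, alternative = alt)$p.value,
        tolerance = 1e-10)
    }
  }
})

test_that("unique-regulation exclusivity helper builds a sane 2x2 table", {
  s <- hcsc_target_summary()
  net <- build_network(candidate_interactions(expand_summary_interactions(s)))
  res <- nod_exclusivity_test(net)
  expect_equal(dim(res$table), c(2, 2))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # expanded placeholder genes each have one regulator, so all are unique
  expect_equal(sum(res$table[, "shared"]), 0)
})

test_that("tripartite assembly adds pathway nodes and membership edges", {
  cand <- data.frame(mirna_id = c("mA", "mA", "mB"),
                     gene_id = c("g1", "g2", "g2"),
                     mirna_direction = "up", gene_direction = "down",
                     stringsAsFactors = FALSE)
  net <- build_network(cand)
  no_enrich <- assemble_tripartite(net, data.frame())
  expect_equal(nrow(no_enrich$edges), nrow(net$edges))

  enr <- data.frame(pathway_id = "pw1", pathway_name = "pw one",
                    stringsAsFactors = FALSE)
  enr$overlap_genes <- list(c("g1", "g2"))
  tri <- assemble_tripartite(net, enr)
  expect_equal(sum(tri$nodes$type == "pathway"), 1)
  expect_equal(sum(tri$edges$relation == "member_of"), 2)
  # genes uniquely regulated by one miRNA are flagged
  flagged <- tri$nodes$id[tri$nodes$unique_regulator]
  expect_identical(flagged, "g1")

  bad <- enr
  bad$overlap_genes <- list("gX")
  expect_error(assemble_tripartite(net, bad), "gX")
})

test_that("interaction summary regenerates the reference table", {
  s <- hcsc_target_summary()
  ints <- expand_summary_interactions(s)
  cand <- candidate_interactions(ints)
  de_m <- structure(list(up = sort(s$mirna_id[s$direction == "up"]),
                         down = sort(s$mirna_id[s$direction == "down"])),
                    class = "consistent_sets")
  # consensus stand-in: expanded interactions plus per-miRNA filler rows
  # so that total_predicted matches the reference counts
  filler <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    extra <- s$total_predicted[i] - s$de_targets[i]
    data.frame(mirna_id = s$mirna_id[i],
               gene_id = paste0(s$mirna_id[i], ":nonde", seq_len(extra)),
               stringsAsFactors = FALSE)
  }))
  consensus <- rbind(ints[, c("mirna_id", "gene_id")], filler)
  out <- summarize_interaction_table(de_m, consensus, ints, cand)
  ref <- s[order(match(s$direction, c("down", "up")), s$mirna_id), ]
  rownames(ref) <- NULL
  expect_equal(out$mirna_id, ref$mirna_id)
  expect_equal(out$total_predicted, ref$total_predicted)
  expect_equal(out$de_targets, ref$de_targets)
  expect_equal(out$up_de_targets, ref$up_de_targets)
  expect_equal(out$down_de_targets, ref$down_de_targets)
  expect_equal(out$candidate_targets, ref$candidate_targets)
  # zero-DE miRNAs keep their all-zero rows
  expect_true(all(c("hsa-miR-378d", "hsa-miR-1269b") %in% out$mirna_id))
})
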