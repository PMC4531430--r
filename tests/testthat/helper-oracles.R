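# Independent oracles used across the suite. Each is written as plain,
# slow, direct computation so it cannot share a defect with the package
# implementation it checks.

# Direct-summation oracle for the Poisson tag-count test: accumulates the
# predictive pmf P(Y = k | x) term by term (recurrence in plain doubles),
# summing each tail directly from k = 0 upward resp. from k = y upward
# until the remaining mass is negligible.
oracle_poisson_p <- function(x, y, N1, N2) {
  r <- N2 / N1
  step <- function(term, k) term * r * (x + k + 1) / ((k + 1) * (1 + r))
  # forward pass to k = y gives the lower tail and the term at y
  term <- (1 / (1 + r))^(x + 1)   # k = 0
  p_le <- 0
  for (k in 0:y) {
    p_le <- p_le + term
    term_y <- term
    term <- step(term, k)
  }
  # upper tail summed directly from y upward
  mode_k <- (x + 1) * r
  p_ge <- 0
  term <- term_y
  k <- y
  repeat {
    p_ge <- p_ge + term
    if (k > mode_k && (term < p_ge * 1e-17 || term == 0)) break
    term <- step(term, k)
    k <- k + 1
    if (k > y + 1e7) stop("oracle failed to converge")
  }
  min(1, 2 * min(p_le, p_ge))
}

# Hand-executed BH step-up: adjusted_(i) = min_{j >= i} p_(j) * m / j,
# capped at 1, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Full-enumeration oracle for the exact 2x2 test: point probabilities via
# dhyper over every table with the observed margins.
oracle_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_hyper_upper <- function(k, n, K, N) {
  ks <- k:min(n, K)
  sum(dhyper(ks, K, N - K, n))
}

# Union-find oracle for connected components over an undirected edge list.
oracle_component_count <- function(nodes, from, to) {
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    ri <- find(match(from[e], nodes))
    rj <- find(match(to[e], nodes))
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_along(nodes), find, 1L)))
}

# Per-gene in-degree scan oracle for NOD.
oracle_nod <- function(mirnas, edges) {
  sapply(mirnas, function(m) {
    genes <- edges$gene_id[edges$mirna_id == m]
    sum(vapply(genes, function(g)
      sum(edges$gene_id == g) == 1, TRUE))
  })
}

# Random bipartite miRNA->gene edge set.
random_bipartite <- function(n_mirnas, n_genes, p_edge) {
  grid <- expand.grid(mirna_id = sprintf("m%02d", seq_len(n_mirnas)),
                      gene_id = sprintf("g%03d", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < p_edge
  grid[keep, , drop = FALSE]
}

random_count_table <- function(feature_class = "miRNA", n_features = 8,
                               n_samples = 3) {
  counts <- matrix(rpois(n_features * n_samples, 50),
                   n_features, n_samples,
                   dimnames = list(sprintf("f%02d", seq_len(n_features)),
                                   sprintf("s%d", seq_len(n_samples))))
  lens <- if (feature_class == "gene")
    setNames(sample(500:3000, n_features, replace = TRUE),
             rownames(counts))
  else NULL
  count_table(counts, feature_class = feature_class,
              feature_lengths = lens)
}

# Hand-made truth object sufficient for simulate_gene_sets /
# simulate_prediction_sources, bypassing the count simulation.
toy_truth <- function(n_genes = 2000, n_cand = 45,
                      mirna = "mirX") {
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  cand_genes <- sample(gene_ids, n_cand)
  cand <- data.frame(mirna_id = mirna, gene_id = cand_genes,
                     mirna_direction = "up", gene_direction = "down",
                     stringsAsFactors = FALSE)
  list(gene_ids = gene_ids, mirna_ids = mirna,
       targets = cand[, c("mirna_id", "gene_id")], candidates = cand)
}
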