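test_that("tag-count test handles symmetric and degenerate cases", {
  expect_equal(poisson_tagcount_p(0, 0, 1e6, 1e6), 1.0)
  expect_equal(poisson_tagcount_p(5, 0, 1e6, 1e6),
               oracle_poisson_p(5, 0, 1e6, 1e6), tolerance = 1e-14)
  expect_error(poisson_tagcount_p(1.5, 2, 1e6, 1e6), "integer")
  expect_error(poisson_tagcount_p(1, 2, 0, 1e6), "positive")
})

test_that("tag-count test agrees with the direct-summation oracle", {
  withr::local_seed(101)
  for (i in 1:200) {
    x <- sample(0:60, 1); y <- sample(0:60, 1)
    r <- sample(c(0.5, 1, 2, 1.7), 1)
    expect_equal(poisson_tagcount_p(x, y, 1e6, r * 1e6),
                 oracle_poisson_p(x, y, 1e6, r * 1e6),
                 tolerance = 1e-12)
  }
})

test_that("tag-count test matches the negative-binomial tail identity", {
  # P(Y = k | x) is NB(size = x + 1, prob = 1/(1+r)); an independent route
  # to both tails.
  withr::local_seed(102)
  for (i in 1:200) {
    x <- sample(0:2000, 1); y <- sample(0:2000, 1)
    r <- runif(1, 0.3, 3)
    p_le <- pnbinom(y, size = x + 1, prob = 1 / (1 + r))
    p_ge <- 1 - pnbinom(y - 1, size = x + 1, prob = 1 / (1 + r))
    ref <- min(1, 2 * min(p_le, p_ge))
    expect_equal(poisson_tagcount_p(x, y, 1e6, r * 1e6), ref,
                 tolerance = 1e-9)
  }
})

test_that("tag-count test matches the oracle in both orientations", {
  # The predictive distribution conditions on the first count, so the
  # test is not an exactly symmetric function of the two libraries; both
  # orientations must nonetheless match the direct-summation oracle.
  withr::local_seed(103)
  for (i in 1:1000) {
    x <- sample(0:40, 1); y <- sample(0:40, 1)
    N1 <- sample(c(5e5, 1e6, 2e6), 1); N2 <- sample(c(5e5, 1e6, 2e6), 1)
    expect_equal(poisson_tagcount_p(x, y, N1, N2),
                 oracle_poisson_p(x, y, N1, N2), tolerance = 1e-9)
    expect_equal(poisson_tagcount_p(y, x, N2, N1),
                 oracle_poisson_p(y, x, N2, N1), tolerance = 1e-9)
  }
})

test_that("tag-count test is stable at deep-sequencing magnitudes", {
  p <- poisson_tagcount_p(c(150000, 200000), c(150123, 100000),
                          1.5e7, 1.5e7)
  expect_true(all(is.finite(p)) && all(p >= 0) && all(p <= 1))
  expect_lt(p[2], 1e-100)  # 2-fold change at 2e5 tags is overwhelming
  expect_gt(p[1], 0.5)     # ~0.08% change at 1.5e5 tags is noise
})

test_that("BH adjustment equals the closed-form step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
  withr::local_seed(21)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
    expect_true(all(bh_adjust(p) <= 1) && all(bh_adjust(p) >= p))
  }
})

make_pair_table <- function(x, y, N = 1e6) {
  counts <- cbind(stem = x, cancer = y)
  rownames(counts) <- sprintf("f%03d", seq_along(x))
  count_table(counts, "miRNA", library_sizes = c(stem = N, cancer = N))
}

test_that("direction calls respect inclusive thresholds", {
  withr::local_seed(31)
  x <- c(4000, 50, rpois(200, 100))
  y <- c(1000, 50, rpois(200, 100))
  tab <- make_pair_table(x, y)
  calls <- call_de(tab, "stem", "cancer")
  expect_identical(calls$direction[1], "up")
  expect_identical(calls$direction[2], "none")
  expect_equal(calls$log2fc[2], 0)

  # boundary inclusivity: |log2fc| exactly at the threshold still counts,
  # and fdr equal to max_fdr still counts
  tab2 <- make_pair_table(c(40, rep(100, 50)), c(15, rep(100, 50)))
  calls2 <- call_de(tab2, "stem", "cancer", threshold_config(pseudocount = 1))
  expect_true(calls2$fdr[1] > 0 && calls2$fdr[1] < 1)
  # re-call with thresholds set to the exactly achieved values: a feature
  # sitting on both boundaries must still be significant
  exact <- threshold_config(min_abs_log2fc = calls2$log2fc[1],
                            max_fdr = calls2$fdr[1], pseudocount = 1)
  calls3 <- call_de(tab2, "stem", "cancer", exact)
  expect_identical(calls3$direction[1], "up")

  expect_error(call_de(tab, "stem", "nope"), "nope")
})

test_that("fold changes use pseudocounted normalized values", {
  tab <- make_pair_table(c(0, 10), c(10, 0), N = 1e6)
  calls <- call_de(tab, "stem", "cancer",
                   threshold_config(pseudocount = 0.5))
  expect_equal(calls$log2fc, c(log2(0.5 / 10.5), log2(10.5 / 0.5)))
  expect_true(all(is.finite(calls$log2fc)))
})

test_that("consistent feature intersection follows both-pair logic", {
  mk <- function(dir) data.frame(feature_id = c("a", "b", "c"),
                                 direction = dir,
                                 stringsAsFactors = FALSE)
  # up only in different features -> empty intersection
  cs <- consistent_features(mk(c("up", "none", "none")),
                            mk(c("none", "up", "none")))
  expect_length(cs$up, 0)
  # discordant feature excluded from both sets
  cs <- consistent_features(mk(c("up", "down", "down")),
                            mk(c("down", "down", "up")))
  expect_length(cs$up, 0)
  expect_identical(cs$down, "b")
  expect_error(consistent_features(mk("up")[1:2, ], mk("up")),
               "c")
})

test_that("consistent set sizes match a brute-force scan on random calls", {
  withr::local_seed(41)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    ids <- sprintf("f%03d", 1:n)
    d1 <- sample(c("up", "down", "none"), n, replace = TRUE)
    d2 <- sample(c("up", "down", "none"), n, replace = TRUE)
    # second call table in shuffled feature order
    shuf <- sample(n)
    cs <- consistent_features(
      data.frame(feature_id = ids, direction = d1,
                 stringsAsFactors = FALSE),
      data.frame(feature_id = ids[shuf], direction = d2[shuf],
                 stringsAsFactors = FALSE))
    brute <- sum(vapply(seq_len(n), function(j)
      d1[j] != "none" && d1[j] == d2[j], TRUE))
    expect_equal(length(cs$up) + length(cs$down), brute)
    expect_length(intersect(cs$up, cs$down), 0)
  }
})
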