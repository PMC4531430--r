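# Exact Poisson-model test for comparing two tag counts (Audic-Claverie
# posterior-predictive form). Given count x in a library of size N1, the
# predictive distribution of the count y in a library of size N2 under a
# shared Poisson rate is, with r = N2/N1:
#
#   P(Y = k | x) = r^k (x+k)! / (x! k! (1+r)^{x+k+1})
#
# i.e. a negative binomial with size x+1 and success probability 1/(1+r).
# The two-sided p-value doubles the smaller tail and caps at 1.

log_predictive_term <- function(k, x, log_r, log_1pr) {
  k * log_r + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log_1pr
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

# Tail mass summed in log space, chunked away from y, with early
# termination once a whole chunk is negligible relative to the running
# total (relative cutoff exp(-45) ~ 3e-20).
predictive_tail <- function(x, y, log_r, log_1pr, direction,
                            chunk = 256L) {
  total <- -Inf
  k0 <- y
  repeat {
    ks <- if (direction == "lower") seq(k0, max(0, k0 - chunk + 1L))
          else seq(k0, k0 + chunk - 1L)
    lt <- log_predictive_term(ks, x, log_r, log_1pr)
    total <- logsumexp(c(total, lt))
    if (direction == "lower" && ks[length(ks)] == 0) break
    if (max(lt) < total - 45) break
    k0 <- if (direction == "lower") ks[length(ks)] - 1L
          else ks[length(ks)] + 1L
  }
  exp(total)
}

poisson_tagcount_p_one <- function(x, y, N1, N2) {
  r <- N2 / N1
  log_r <- log(r)
  log_1pr <- log1p(r)
  pmf_y <- exp(log_predictive_term(y, x, log_r, log_1pr))
  mean_y <- (x + 1) * r
  if (y <= mean_y) {
    p_le <- predictive_tail(x, y, log_r, log_1pr, "lower")
    p_ge <- 1 - p_le + pmf_y
  } else {
    p_ge <- predictive_tail(x, y, log_r, log_1pr, "upper")
    p_le <- 1 - p_ge + pmf_y
  }
  p_le <- min(max(p_le, 0), 1)
  p_ge <- min(max(p_ge, 0), 1)
  min(1, 2 * min(p_le, p_ge))
}

#' Exact Poisson test for two tag counts
#'
#' Tests whether a tag count `x` observed in a library of `N1` total mapped
#' reads and a count `y` in a library of `N2` reads are consistent with a
#' common underlying Poisson rate. The predictive distribution of `y`
#' given `x` with library-size ratio `r = N2/N1` is
#' `P(Y = k | x) = r^k (x+k)! / (x! k! (1+r)^(x+k+1))`; the two-sided
#' p-value is `min(1, 2 * min(P(Y <= y), P(Y >= y)))`. Tail masses are
#' accumulated in log space (the shorter tail summed directly with early
#' termination, the longer tail as its complement) so the test is stable
#' at deep-sequencing count magnitudes.
#'
#' @param x,y non-negative integer counts (vectorized; recycled).
#' @param N1,N2 positive library sizes (total mapped reads) for the
#'   libraries of `x` and `y` respectively.
#' @return Numeric vector of two-sided p-values in `[0, 1]`.
#' @examples
#' poisson_tagcount_p(5, 25, 1e6, 1e6)
#' @export
poisson_tagcount_p <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y)))
    stop("counts must be non-negative integers")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library sizes must be positive")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i)
    poisson_tagcount_p_one(x[i], y[i], N1[i], N2[i]), 0.0)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper over the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`): adjusted value i (in p-sorted
#' order) is `min_{j >= i}(p_(j) * m / j)`, capped at 1, returned in the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
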