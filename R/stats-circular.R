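#' Circular mean, resultant length and circular standard deviation
#'
#' First-trigonometric-moment statistics for angles in radians. The mean
#' direction is undefined (NA, flagged) when the resultant length is
#' numerically zero; the circular sd is sqrt(-2 log R).
#'
#' @param angles radians.
#' @return list: `mean` (radians, NA if undefined), `R` (resultant
#'   length in \[0, 1\]), `sd` (radians), `n`, `defined`.
#' @export
circularMeanSd <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (!length(angles)) .stopf("empty angle sample")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  defined <- R > 1e-12
  list(mean = if (defined) atan2(S, C) else NA_real_,
       R = R,
       sd = if (defined) sqrt(-2 * log(min(R, 1))) else Inf,
       n = length(angles), defined = defined)
}

#' Watson's two-sample U-squared test of homogeneity
#'
#' Rotation-invariant two-sample test for circular data:
#' U2 = (n m / N^2) sum_k (d_k - mean(d))^2 with d_k the difference of
#' the two sample ECDFs at the k-th pooled order statistic. The p-value
#' is the asymptotic series P(U2 > u) = 2 sum_{j>=1} (-1)^{j-1}
#' exp(-2 j^2 pi^2 u) when both samples have at least `minAsymptotic`
#' observations, otherwise (or on request) a seeded permutation p.
#'
#' @param a,b angle samples, radians.
#' @param pMethod `"auto"`, `"asymptotic"` or `"permutation"`.
#' @param nPerm permutation resamples.
#' @param minAsymptotic minimum per-sample n for the asymptotic p.
#' @param seed seed for the permutation stream.
#' @return object of class `htest` with `statistic` (U2) and `p.value`.
#' @export
watsonU2 <- function(a, b, pMethod = c("auto", "asymptotic", "permutation"),
                     nPerm = 1999L, minAsymptotic = 8L, seed = 1L) {
  pMethod <- match.arg(pMethod)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    .stopf("degenerate error: need >= 2 distinct angles per sample")
  na <- length(a); nb <- length(b)
  pooled <- c(a %% (2 * pi), b %% (2 * pi))
  ord <- order(pooled)
  lab <- as.integer(c(rep(1L, na), rep(0L, nb))[ord])
  U2 <- .cpp_watson_stat(lab, na, nb)
  if (pMethod == "auto")
    pMethod <- if (min(na, nb) >= minAsymptotic) "asymptotic" else
      "permutation"
  if (pMethod == "asymptotic") {
    j <- seq_len(60)
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * pi^2 * U2))
    p <- min(1, max(0, p))
  } else {
    set.seed(seed)
    hits <- .cpp_watson_perm_count(na, nb, as.integer(nPerm), U2)
    p <- (1 + hits) / (nPerm + 1)
  }
  structure(list(statistic = c(U2 = U2), p.value = p,
                 method = sprintf(
                   "Watson's two-sample U2 test (%s p)", pMethod),
                 data.name = "a vs b",
                 sample.sizes = c(na, nb), p.method = pMethod),
            class = "htest")
}

#' Welch's two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] with unequal variances
#' (Satterthwaite degrees of freedom), returning the pieces the
#' reporting layer uses.
#'
#' @param a,b numeric samples.
#' @return list: `t`, `df`, `p.value`, `estimate` (mean difference).
#' @export
welchT <- function(a, b) {
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value,
       estimate = unname(ht$estimate[1L] - ht$estimate[2L]))
}
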