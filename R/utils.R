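`%||%` <- function(a, b) if (is.null(a)) b else a

.um <- 1e-6 # metres per micrometre

#' Derive a reproducible child seed from a master seed and a label
#'
#' Keeps one RNG stream per embryo so datasets are reproducible
#' element-wise regardless of how many embryos are generated.
#' @keywords internal
.childSeed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) *
             seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Nonparametric bootstrap over sampling units (cells or vessels),
#' percentile method.
#'
#' @param x numeric vector of per-unit values (NAs dropped).
#' @param n number of resamples.
#' @param level confidence level.
#' @param seed integer seed for the resampling stream.
#' @return named numeric: mean, lower, upper, n.
#' @export
bootstrapCI <- function(x, n = 2000L, level = 0.95, seed = 1L) {
  x <- unname(x[is.finite(x)])
  if (length(x) == 0L)
    return(c(mean = NA_real_, lower = NA_real_, upper = NA_real_, n = 0))
  if (length(x) == 1L)
    return(c(mean = x, lower = x, upper = x, n = 1))
  set.seed(seed)
  idx <- matrix(sample.int(length(x), length(x) * n, replace = TRUE),
                nrow = length(x))
  means <- colMeans(matrix(x[idx], nrow = length(x)))
  a <- (1 - level) / 2
  q <- unname(quantile(means, c(a, 1 - a), names = FALSE, type = 7))
  c(mean = mean(x), lower = q[1L], upper = q[2L], n = length(x))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
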