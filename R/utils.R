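#' Sample skewness (biased moment estimator)
#'
#' Computes g1 = m3 / m2^(3/2) with central moments using 1/n denominators.
#' This is the plain moment estimator, without small-sample correction.
#'
#' @param x numeric vector; NAs are dropped.
#' @return a single numeric value, NA if fewer than 2 distinct values.
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) return(NA_real_)
  mean(d^3) / m2^1.5
}

#' Percentage of expressed genes that switch
#'
#' Convenience summary used in reports: 100 * (n_on + n_off) / n_expressed.
#'
#' @param n_on,n_off numbers of switch-on and switch-off genes.
#' @param n_expressed number of expressed genes in the universe.
#' @return percentage (0-100).
#' @export
switch_gene_percentage <- function(n_on, n_off, n_expressed) {
  stopifnot(n_expressed > 0, n_on >= 0, n_off >= 0)
  100 * (n_on + n_off) / n_expressed
}

# internal: stop unless x is a whole number matrix with no negatives
assert_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[i[1L]] %||% i[1L],
                 colnames(counts)[i[2L]] %||% i[2L]))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: derive a child seed for a pipeline stage from the global seed.
# Documented derivation: (seed + 9973 * stage_index) mod (2^31 - 1), so each
# stage has an independent, reproducible stream.
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 9973 * stage_index) %% 2147483647)
}
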