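# Expression preprocessing: RPKM -> per-gene outlier masking -> day means ->
# skewness-guided expression threshold -> log2 with a jittered pseudocount.
# Stages are order-enforced; each function tags its output with a stage label
# and refuses input from the wrong stage.

expr_stages <- c("rpkm", "outlier_removed", "day_mean", "thresholded", "log2")

# internal: construct an expression matrix at a given stage
expr_matrix <- function(values, stage, day = NULL) {
  stopifnot(stage %in% expr_stages, is.matrix(values))
  structure(list(values = values, stage = stage, day = day), class = "expr_matrix")
}

# internal: check the stage of an input
require_stage <- function(x, stage) {
  if (!inherits(x, "expr_matrix"))
    stop("expected an expr_matrix; run rpkm() first")
  if (x$stage != stage)
    stop(sprintf("stage order violated: expected a '%s' matrix, got '%s'",
                 stage, x$stage))
  invisible(TRUE)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d columns\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM = count * 1e9 / (gene_length_bp * library_size)` with library size
#' the column sum of counts, so values are invariant to uniform depth scaling
#' of a sample.
#'
#' @param counts a [count_matrix()].
#' @return an `expr_matrix` at stage `"rpkm"` (genes x samples).
#' @export
rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  lib <- colSums(counts$counts)
  if (any(lib == 0))
    stop(sprintf("zero library size in sample '%s'",
                 colnames(counts$counts)[which(lib == 0)[1L]]))
  v <- sweep(counts$counts * 1e9 / counts$gene_length, 2, lib, "/")
  expr_matrix(v, "rpkm", day = counts$day)
}

#' Mask the per-gene maximum value as an outlier
#'
#' For every gene the single highest value across all samples is marked
#' missing (on ties, the first in sample order); all other values are kept.
#' This is a masking rule, not gene removal: the affected day then averages
#' over the remaining replicates.
#'
#' @param x an `expr_matrix` at stage `"rpkm"`.
#' @return an `expr_matrix` at stage `"outlier_removed"` with one NA per gene.
#' @export
remove_gene_outlier <- function(x) {
  require_stage(x, "rpkm")
  if (ncol(x$values) < 2L) stop("need at least 2 samples")
  v <- x$values
  v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))] <- NA_real_
  expr_matrix(v, "outlier_removed", day = x$day)
}

#' Average replicates within each day
#'
#' @param x an `expr_matrix` at stage `"outlier_removed"` with day labels.
#' @return an `expr_matrix` at stage `"day_mean"` (genes x days), columns
#'   named `P<day>` and ordered by day.
#' @export
day_means <- function(x) {
  require_stage(x, "outlier_removed")
  if (is.null(x$day)) stop("day labels required")
  days <- sort(unique(x$day))
  v <- do.call(cbind, lapply(days, function(d)
    rowMeans(x$values[, x$day == d, drop = FALSE], na.rm = TRUE)))
  if (anyNA(v) || any(!is.finite(v)))
    stop("a gene-day with all values missing")
  colnames(v) <- paste0("P", days)
  rownames(v) <- rownames(x$values)
  expr_matrix(v, "day_mean", day = days)
}

#' Choose an expression threshold by skewness of the retained distribution
#'
#' For each candidate threshold `t`, genes whose maximum day-mean RPKM is at
#' least `t` are retained and the sample skewness `g1` of the log2 of the
#' retained genes' mean expression is computed; the chosen threshold is the
#' one whose skewness is closest to zero (ties: the smallest threshold).
#' Candidates retaining fewer than 10 genes are skipped with a warning.
#' Genes whose mean expression is zero never enter the skewness sample.
#'
#' @param x an `expr_matrix` at stage `"day_mean"`.
#' @param grid strictly increasing candidate thresholds (RPKM); default
#'   0 to 5 in steps of 0.005.
#' @return list of class `threshold_scan` with `grid`, `skewness`,
#'   `n_retained` and `chosen_threshold`.
#' @export
select_threshold <- function(x, grid = seq(0, 5, by = 0.005)) {
  require_stage(x, "day_mean")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  mx <- apply(x$values, 1, max)
  mn <- rowMeans(x$values)
  keep <- mn > 0
  mx <- mx[keep]
  lg <- log2(mn[keep])
  ord <- order(mx, decreasing = TRUE)
  lg <- lg[ord]
  mxs <- mx[ord]
  # prefix moments over genes sorted by descending max day-mean
  s1 <- cumsum(lg); s2 <- cumsum(lg^2); s3 <- cumsum(lg^3)
  n_at <- length(mxs) - findInterval(grid, sort(mxs), left.open = TRUE)
  g1 <- rep(NA_real_, length(grid))
  ok <- n_at >= 10L
  if (any(!ok)) warning(sprintf("%d candidate thresholds retain fewer than 10 genes; skipped",
                                sum(!ok)))
  k <- n_at[ok]
  m <- s1[k] / k
  m2 <- s2[k] / k - m^2
  m3 <- s3[k] / k - 3 * m * s2[k] / k + 2 * m^3
  g1[ok] <- m3 / m2^1.5
  if (!any(is.finite(g1))) stop("no usable candidate threshold")
  chosen <- grid[which.min(abs(g1))]
  structure(list(grid = grid, skewness = g1, n_retained = n_at,
                 chosen_threshold = chosen),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan: %d candidates, chosen threshold %.3f RPKM (|g1| = %.4f)\n",
              length(x$grid), x$chosen_threshold,
              min(abs(x$skewness), na.rm = TRUE)))
  invisible(x)
}

#' Apply an expression threshold
#'
#' Keeps genes whose maximum day-mean RPKM reaches the threshold; a gene is
#' "expressed" if it ever exceeds the threshold, so genes expressed only
#' before or only after the switch are retained.
#'
#' @param x an `expr_matrix` at stage `"day_mean"`.
#' @param threshold RPKM threshold (for the original study data, 1.645 RPKM;
#'   use [select_threshold()] to derive one from the data at hand).
#' @return an `expr_matrix` at stage `"thresholded"`.
#' @export
apply_threshold <- function(x, threshold) {
  require_stage(x, "day_mean")
  keep <- apply(x$values, 1, max) >= threshold
  if (!any(keep)) stop("threshold removes every gene")
  expr_matrix(x$values[keep, , drop = FALSE], "thresholded", day = x$day)
}

#' log2 transform with a jittered pseudocount for zeros
#'
#' Every zero is replaced by the global minimum nonzero value plus an
#' independent draw of `U{1..10} / 1e6`, then the matrix is log2 transformed;
#' the output is finite everywhere.
#'
#' @param x an `expr_matrix` at stage `"thresholded"`.
#' @param seed integer seed for the jitter draws.
#' @return an `expr_matrix` at stage `"log2"`.
#' @export
log2_with_jittered_pseudocount <- function(x, seed = 1L) {
  require_stage(x, "thresholded")
  v <- x$values
  nz <- v[v > 0]
  if (!length(nz)) stop("all-zero matrix")
  zeros <- which(v == 0)
  if (length(zeros)) {
    set.seed(seed)
    v[zeros] <- min(nz) + sample.int(10L, length(zeros), replace = TRUE) / 1e6
  }
  expr_matrix(log2(v), "log2", day = x$day)
}

#' Run the full expression preprocessing chain
#'
#' Convenience wrapper: RPKM, per-gene outlier masking, day means, threshold
#' selection (or a fixed threshold), thresholding, and the jittered-pseudocount
#' log2 transform.
#'
#' @param counts a [count_matrix()].
#' @param threshold `"auto"` (default) to choose by [select_threshold()], or a
#'   fixed RPKM value.
#' @param grid candidate grid for the automatic threshold.
#' @param seed seed for the pseudocount jitter.
#' @return list with `log2_expr` (stage `"log2"` matrix, genes x days),
#'   `day_mean` (pre-threshold day means), `scan` (the threshold scan or NULL)
#'   and `threshold`.
#' @export
prep_expression <- function(counts, threshold = "auto",
                            grid = seq(0, 5, by = 0.005), seed = 1L) {
  dm <- day_means(remove_gene_outlier(rpkm(counts)))
  scan <- NULL
  if (identical(threshold, "auto")) {
    scan <- select_threshold(dm, grid)
    threshold <- scan$chosen_threshold
  }
  thr <- apply_threshold(dm, threshold)
  list(log2_expr = log2_with_jittered_pseudocount(thr, seed = seed),
       day_mean = dm, scan = scan, threshold = threshold)
}
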