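# Exon-intron split analysis: exonic reads sample both pre-mRNA and mature
# mRNA, intronic reads only pre-mRNA; correlated pre/post changes in the two
# attribute the expression switch to transcription.

#' Per-gene exonic and intronic log2 changes between the expression windows
#'
#' Each matrix is depth-normalized to counts per million, a pseudocount of 1
#' is added, values are log2 transformed and averaged over the samples of
#' each window; the delta is post minus pre. Genes whose summed raw counts in
#' any window of either matrix fall below `min_count` are excluded (guards
#' against log-of-noise for intron-poor genes) and counted.
#'
#' @param exonic,intronic [count_matrix()] objects sharing gene and sample ids.
#' @param pre_days,post_days day windows (switch day in neither).
#' @param min_count minimum summed raw reads per window per matrix; set to 0
#'   to disable the filter.
#' @return list with `deltas` (data.frame: gene_id, delta_exon, delta_intron)
#'   and `n_excluded`.
#' @export
split_deltas <- function(exonic, intronic, pre_days = 0:5, post_days = 7:12,
                         min_count = 8) {
  stopifnot(inherits(exonic, "count_matrix"), inherits(intronic, "count_matrix"))
  if (!identical(rownames(exonic$counts), rownames(intronic$counts)) ||
      !identical(colnames(exonic$counts), colnames(intronic$counts)))
    stop("exonic and intronic matrices must share gene ids and samples")
  if (length(intersect(pre_days, post_days))) stop("overlapping windows")
  pre <- exonic$day %in% pre_days
  post <- exonic$day %in% post_days
  if (!any(pre) || !any(post)) stop("windows must select at least one sample each")

  window_delta <- function(cm) {
    cpm <- sweep(cm$counts, 2, colSums(cm$counts) / 1e6, "/")
    lg <- log2(cpm + 1)
    rowMeans(lg[, post, drop = FALSE]) - rowMeans(lg[, pre, drop = FALSE])
  }
  window_ok <- function(cm) {
    rowSums(cm$counts[, pre, drop = FALSE]) >= min_count &
      rowSums(cm$counts[, post, drop = FALSE]) >= min_count
  }
  keep <- window_ok(exonic) & window_ok(intronic)
  deltas <- data.frame(gene_id = rownames(exonic$counts),
                       delta_exon = window_delta(exonic),
                       delta_intron = window_delta(intronic),
                       stringsAsFactors = FALSE)[keep, ]
  rownames(deltas) <- NULL
  list(deltas = deltas, n_excluded = sum(!keep))
}

#' Transcriptional attribution from exon-intron deltas
#'
#' Pearson correlation between the exonic and intronic log2 changes across
#' genes; its square is reported as the fraction of the expression change
#' attributable to transcription.
#'
#' @param deltas result of [split_deltas()] (or its `deltas` data.frame).
#' @return list of class `eisa_result` with `pearson_r`,
#'   `transcriptional_fraction` (= r^2), `n_genes`, `n_excluded`.
#' @export
transcriptional_fraction <- function(deltas) {
  n_excluded <- 0L
  if (is.list(deltas) && !is.data.frame(deltas)) {
    n_excluded <- deltas$n_excluded %||% 0L
    deltas <- deltas$deltas
  }
  if (nrow(deltas) < 10L) stop("need at least 10 genes with both deltas")
  if (stats::sd(deltas$delta_exon) == 0 || stats::sd(deltas$delta_intron) == 0)
    stop("zero variance in a delta vector")
  r <- stats::cor(deltas$delta_exon, deltas$delta_intron)
  structure(list(pearson_r = r, transcriptional_fraction = r^2,
                 n_genes = nrow(deltas), n_excluded = n_excluded),
            class = "eisa_result")
}

#' @export
print.eisa_result <- function(x, ...) {
  cat(sprintf("EISA: Pearson r = %.3f over %d genes (%d excluded); transcription accounts for >= %.1f%% of the change\n",
              x$pearson_r, x$n_genes, x$n_excluded,
              100 * x$transcriptional_fraction))
  invisible(x)
}
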