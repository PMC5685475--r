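# Switch detection and classification: sample correlations, day-level PCA,
# pre/post fold changes, a native negative-binomial likelihood-ratio test,
# class labels and normalized class time courses.

#' Pearson correlation matrix between samples
#'
#' @param log_expr numeric matrix, genes x samples (log2 scale).
#' @return symmetric samples x samples correlation matrix with unit diagonal.
#' @export
sample_correlations <- function(log_expr) {
  stopifnot(is.matrix(log_expr))
  if (ncol(log_expr) < 2L) stop("need at least 2 samples")
  sds <- apply(log_expr, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("zero-variance sample '%s'",
                 colnames(log_expr)[which(sds == 0)[1L]] %||% which(sds == 0)[1L]))
  stats::cor(log_expr)
}

#' Principal component analysis of the day-level time course
#'
#' Days are the observations and genes the variables: each gene (column of
#' the transposed matrix) is centered, then an SVD yields per-day component
#' scores and the fraction of variance per component. The sign convention
#' fixes each component's score at the earliest day to be non-positive.
#'
#' @param log_expr an `expr_matrix` at stage `"log2"` (genes x days) or a
#'   plain genes x days matrix.
#' @return list of class `pca_timecourse` with `scores` (days x components),
#'   `loadings` (genes x components), `variance_fraction` and `days`.
#' @export
pca_timecourse <- function(log_expr) {
  v <- if (inherits(log_expr, "expr_matrix")) log_expr$values else log_expr
  days <- if (inherits(log_expr, "expr_matrix")) log_expr$day else
    as.integer(sub("^P", "", colnames(v)))
  if (ncol(v) < 3L) stop("need at least 3 days")
  x <- t(v)                                  # days x genes
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  flip <- scores[1L, ] > 0
  scores[, flip] <- -scores[, flip]
  loadings[, flip] <- -loadings[, flip]
  vf <- sv$d^2 / sum(sv$d^2)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_along(vf)))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = vf, days = days),
            class = "pca_timecourse")
}

#' @export
print.pca_timecourse <- function(x, ...) {
  cat(sprintf("pca_timecourse: PC1 %.1f%%, PC2 %.1f%% of variance over %d days\n",
              100 * x$variance_fraction[1], 100 * x$variance_fraction[2],
              nrow(x$scores)))
  invisible(x)
}

#' Per-gene log2 fold change between the pre- and post-switch windows
#'
#' `log2_fc = mean over post days - mean over pre days` of log2 expression.
#' The switch day itself (day 6 by default) belongs to neither window.
#'
#' @param log_expr an `expr_matrix` at stage `"log2"` or genes x days matrix
#'   with `P<day>` column names.
#' @param pre_days,post_days disjoint, non-empty day windows.
#' @return named numeric vector of per-gene log2 fold changes.
#' @export
fold_changes <- function(log_expr, pre_days = 0:5, post_days = 7:12) {
  v <- if (inherits(log_expr, "expr_matrix")) log_expr$values else log_expr
  days <- if (inherits(log_expr, "expr_matrix")) log_expr$day else
    as.integer(sub("^P", "", colnames(v)))
  if (!length(pre_days) || !length(post_days)) stop("both windows must be non-empty")
  if (length(intersect(pre_days, post_days))) stop("overlapping windows")
  pre <- days %in% pre_days
  post <- days %in% post_days
  if (!any(pre) || !any(post)) stop("windows must select at least one day each")
  rowMeans(v[, post, drop = FALSE]) - rowMeans(v[, pre, drop = FALSE])
}

#' Negative-binomial likelihood-ratio test for a two-group difference
#'
#' Per gene, a negative-binomial GLM with log link and log-library-size
#' offsets is fitted under the full model (one mean per group) and the null
#' (one common mean); the statistic `2 * (ll_full - ll_null)` is referred to
#' a chi-square with 1 df. The per-gene dispersion is a moment estimator
#' shrunk 50/50 toward the 10%-trimmed-mean common dispersion. Genes with
#' all-zero counts get p = 1 and are flagged. FDR is Benjamini-Hochberg.
#'
#' @param counts integer matrix, genes x samples (raw counts).
#' @param group two-level factor or vector, one entry per sample.
#' @param dispersion optional fixed dispersion (scalar or per gene) that
#'   bypasses estimation; useful for calibration studies.
#' @param lib_sizes optional per-sample library sizes for the offsets;
#'   defaults to the column sums of `counts`.
#' @return data.frame with `gene_id`, `dispersion`, `lrt_stat`, `p_value`,
#'   `fdr`, `flagged`.
#' @export
nb_lrt_test <- function(counts, group, dispersion = NULL, lib_sizes = NULL) {
  stopifnot(is.matrix(counts))
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (any(table(group) < 2L)) stop("need at least 2 samples per group")
  lib <- lib_sizes %||% colSums(counts)
  if (any(lib <= 0)) stop("zero library size")
  offset <- log(lib)
  if (is.null(dispersion)) dispersion <- estimate_dispersions(counts, group, lib)
  dispersion <- rep_len(pmax(dispersion, 1e-12), nrow(counts))

  xf <- stats::model.matrix(~group)
  x0 <- matrix(1, ncol(counts), 1L)
  n <- nrow(counts)
  stat <- numeric(n)
  flagged <- rowSums(counts) == 0
  for (i in seq_len(n)) {
    if (flagged[i]) next
    y <- counts[i, ]
    theta <- 1 / dispersion[i]
    fam <- MASS::negative.binomial(theta)
    ll <- function(x) {
      fit <- suppressWarnings(
        stats::glm.fit(x, y, offset = offset, family = fam,
                       control = list(epsilon = 1e-12, maxit = 100L)))
      sum(stats::dnbinom(y, size = theta, mu = fit$fitted.values, log = TRUE))
    }
    stat[i] <- max(0, 2 * (ll(xf) - ll(x0)))
  }
  p <- ifelse(flagged, 1, stats::pchisq(stat, df = 1L, lower.tail = FALSE))
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(n)),
             dispersion = dispersion, lrt_stat = stat, p_value = p,
             fdr = stats::p.adjust(p, "BH"), flagged = flagged,
             stringsAsFactors = FALSE)
}

# internal: per-gene moment dispersion shrunk toward the trimmed-mean common
# dispersion (weights 0.5 / 0.5)
estimate_dispersions <- function(counts, group, lib = colSums(counts)) {
  sf <- lib / exp(mean(log(lib)))
  q <- sweep(counts, 2, sf, "/")
  num <- den <- numeric(nrow(counts))
  for (g in levels(group)) {
    qg <- q[, group == g, drop = FALSE]
    m <- rowMeans(qg)
    v <- apply(qg, 1, stats::var)
    w <- ncol(qg) - 1L
    ph <- ifelse(m > 0, (v - m) / m^2, NA_real_)
    ok <- is.finite(ph)
    num[ok] <- num[ok] + w * pmin(pmax(ph[ok], 0), 10)
    den[ok] <- den[ok] + w
  }
  phi <- ifelse(den > 0, num / den, NA_real_)
  common <- mean(phi[is.finite(phi)], trim = 0.1)
  if (!is.finite(common)) common <- 0.1
  out <- 0.5 * ifelse(is.finite(phi), phi, common) + 0.5 * common
  pmax(out, 1e-8)
}

#' Classify genes into switch-on, switch-off, constant and other
#'
#' Switch-on: log2 fold change >= 1 at FDR < 0.05; switch-off: <= -1 at
#' FDR < 0.05; constant: |log2 fold change| < 0.01; everything else "other".
#' Also flags the at-least-4-fold (|log2 fc| > 2) subsets used for the
#' fine time-course summaries.
#'
#' @param log2_fc named per-gene log2 fold changes.
#' @param test data.frame from [nb_lrt_test()] aligned by gene id, or NULL to
#'   classify on fold change alone (no FDR gate; switch classes then require
#'   only the fold-change cut).
#' @param fdr_cutoff FDR threshold for the switch classes.
#' @return data.frame of class `switch_table`: `gene_id`, `log2_fc`,
#'   `lrt_stat`, `p_value`, `fdr`, `class`, `strong` (|log2 fc| > 2 switch
#'   gene).
#' @export
classify <- function(log2_fc, test = NULL, fdr_cutoff = 0.05) {
  gene_id <- names(log2_fc) %||% as.character(seq_along(log2_fc))
  if (is.null(test)) {
    fdr <- rep(0, length(log2_fc))
    stat <- p <- rep(NA_real_, length(log2_fc))
  } else {
    idx <- match(gene_id, test$gene_id)
    if (anyNA(idx)) stop("fold changes and test results must align by gene id")
    fdr <- test$fdr[idx]
    stat <- test$lrt_stat[idx]
    p <- test$p_value[idx]
  }
  cls <- ifelse(log2_fc >= 1 & fdr < fdr_cutoff, "switch_on",
         ifelse(log2_fc <= -1 & fdr < fdr_cutoff, "switch_off",
         ifelse(abs(log2_fc) < 0.01, "constant", "other")))
  out <- data.frame(gene_id = gene_id, log2_fc = as.numeric(log2_fc),
                    lrt_stat = stat, p_value = p, fdr = fdr, class = cls,
                    strong = cls %in% c("switch_on", "switch_off") & abs(log2_fc) > 2,
                    stringsAsFactors = FALSE)
  class(out) <- c("switch_table", "data.frame")
  out
}

#' Normalized class time course
#'
#' Per gene, the mean log2 expression over the reference window (pre- or
#' post-switch) is subtracted; the curves are then averaged across the gene
#' set, giving the mean normalized log2 expression per day.
#'
#' @param log_expr an `expr_matrix` at stage `"log2"` or genes x days matrix.
#' @param gene_set non-empty character vector of gene ids.
#' @param reference `"pre"` (default) or `"post"`: which window is subtracted.
#' @param pre_days,post_days the window definitions.
#' @return named numeric vector, one normalized mean per day.
#' @export
normalized_timecourse <- function(log_expr, gene_set, reference = c("pre", "post"),
                                  pre_days = 0:5, post_days = 7:12) {
  reference <- match.arg(reference)
  v <- if (inherits(log_expr, "expr_matrix")) log_expr$values else log_expr
  days <- if (inherits(log_expr, "expr_matrix")) log_expr$day else
    as.integer(sub("^P", "", colnames(v)))
  gene_set <- intersect(gene_set, rownames(v))
  if (!length(gene_set)) stop("empty gene set")
  m <- v[gene_set, , drop = FALSE]
  win <- days %in% (if (reference == "pre") pre_days else post_days)
  colMeans(m - rowMeans(m[, win, drop = FALSE]))
}

#' Chi-square test of the chromosomal distribution of switch genes
#'
#' Observed per-chromosome switch-gene counts are compared with an
#' expectation proportional to all expressed genes; chromosomes with expected
#' count below 5 are pooled.
#'
#' @param switch_genes character vector of switch gene ids (non-empty).
#' @param all_genes character vector of all expressed gene ids.
#' @param annotation gene annotation (list with `genes`, as from
#'   [read_gene_annotation()]).
#' @return `htest`-like list with `statistic`, `p.value`, `observed`,
#'   `expected`.
#' @export
chromosome_distribution_test <- function(switch_genes, all_genes, annotation) {
  if (!length(switch_genes)) stop("empty switch gene set")
  g <- annotation$genes
  chrom_all <- g$chromosome[match(all_genes, g$gene_id)]
  chrom_sw <- g$chromosome[match(switch_genes, g$gene_id)]
  tab_all <- table(chrom_all)
  prop <- as.numeric(tab_all) / sum(tab_all)
  expected <- prop * length(switch_genes)
  pool <- expected < 5
  lev <- names(tab_all)
  chrom_sw2 <- ifelse(chrom_sw %in% lev[pool], "pooled", chrom_sw)
  lev2 <- c(lev[!pool], if (any(pool)) "pooled")
  if (length(lev2) < 2L)
    stop("need at least 2 chromosome classes with expected count >= 5")
  obs <- table(factor(chrom_sw2, levels = lev2))
  prop2 <- c(prop[!pool], if (any(pool)) sum(prop[pool]))
  ht <- stats::chisq.test(as.numeric(obs), p = prop2)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       observed = obs, expected = prop2 * length(switch_genes))
}
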