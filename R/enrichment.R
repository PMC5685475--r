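# Permutation enrichment framework: TF frequency in ranked fold-change bins,
# pathway / cone-gene switch tests, and the draw-count convergence diagnostic.
# Null sets are drawn WITH replacement from the expressed-gene universe, as in
# the original protocol; p-values use the add-one rule so they are never zero,
# and the exact binomial tail is exposed for the frequency test (whose
# with-replacement null is exactly Binomial(bin_size, f)).

# internal: permutation result container
permutation_result <- function(observed_stat, n_draws, n_as_extreme, direction,
                               seed, p_exact = NA_real_, sign = NA_real_) {
  structure(list(observed_stat = observed_stat, n_draws = n_draws,
                 n_as_extreme = n_as_extreme,
                 p_value = (n_as_extreme + 1) / (n_draws + 1),
                 below_resolution = n_as_extreme == 0L,
                 p_exact = p_exact, direction = direction, sign = sign,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): observed %.4g, p = %.3g (%d of %g draws as extreme%s)\n",
              x$direction, x$observed_stat, x$p_value, x$n_as_extreme, x$n_draws,
              if (x$below_resolution) sprintf("; below resolution, p < %.1g", 1 / x$n_draws) else ""))
  if (is.finite(x$p_exact))
    cat(sprintf("  exact binomial tail: %.3g\n", x$p_exact))
  invisible(x)
}

#' Transcription-factor frequency in nested top-N fold-change bins
#'
#' Genes are ranked by log2 fold change (descending for the switch-on
#' direction, ascending for switch-off) and the TF fraction is computed in
#' the nested top-100..600 bins plus the whole universe ("total").
#'
#' @param log2_fc named per-gene log2 fold changes over all expressed genes.
#' @param is_tf named logical (or vector aligned with `log2_fc`).
#' @param direction `"on"` or `"off"`.
#' @param bin_sizes nested bin sizes.
#' @return list of class `bin_series` with `bin_sizes`, `frequency`,
#'   `observed_count` per bin, and `total_frequency`.
#' @export
tf_bin_frequencies <- function(log2_fc, is_tf, direction = c("on", "off"),
                               bin_sizes = c(100L, 200L, 300L, 400L, 500L, 600L)) {
  direction <- match.arg(direction)
  if (!is.null(names(is_tf)) && !is.null(names(log2_fc)))
    is_tf <- is_tf[names(log2_fc)]
  stopifnot(length(is_tf) == length(log2_fc))
  if (max(bin_sizes) > length(log2_fc)) stop("bins larger than universe")
  ord <- order(log2_fc, decreasing = (direction == "on"))
  ranked_tf <- as.logical(is_tf)[ord]
  counts <- vapply(bin_sizes, function(b) sum(ranked_tf[seq_len(b)]), integer(1))
  structure(list(bin_sizes = bin_sizes,
                 frequency = counts / bin_sizes,
                 observed_count = counts,
                 total_frequency = mean(as.logical(is_tf)),
                 direction = direction),
            class = "bin_series")
}

#' Permutation test of TF frequency in a bin (with-replacement null)
#'
#' Each draw samples `bin_size` genes with replacement from the universe and
#' counts TFs; the p-value is the add-one upper tail
#' `(# draws >= observed + 1) / (n_draws + 1)`. Because draws are with
#' replacement the null is exactly Binomial(bin_size, f); the analytic tail
#' is returned alongside the Monte Carlo estimate.
#'
#' @param observed_count TF count observed in the bin.
#' @param bin_size bin size.
#' @param universe_labels logical vector, TF status per universe gene.
#' @param n_draws Monte Carlo draws.
#' @param seed integer seed.
#' @return a `permutation_result` (direction `"greater"`), with `p_exact`.
#' @export
permutation_frequency_test <- function(observed_count, bin_size, universe_labels,
                                       n_draws = 1e6, seed = 1L) {
  universe_labels <- as.logical(universe_labels)
  if (observed_count > bin_size) stop("observed_count exceeds bin_size")
  f <- mean(universe_labels)
  set.seed(seed)
  n_extreme <- 0L
  chunk <- max(1L, floor(2e6 / bin_size))
  left <- n_draws
  while (left > 0) {
    k <- min(chunk, left)
    idx <- sample.int(length(universe_labels), k * bin_size, replace = TRUE)
    stat <- colSums(matrix(universe_labels[idx], nrow = bin_size))
    n_extreme <- n_extreme + sum(stat >= observed_count)
    left <- left - k
  }
  p_exact <- stats::pbinom(observed_count - 1L, bin_size, f, lower.tail = FALSE)
  permutation_result(observed_count, n_draws, n_extreme, "greater", seed,
                     p_exact = p_exact)
}

#' Permutation test of a pathway's mean fold change
#'
#' The statistic is the mean log2 fold change over the pathway genes
#' (non-expressed members are dropped with a warning; the cone-specific set
#' is treated exactly like a pathway). The null distribution is the mean of
#' equal-sized with-replacement draws from all expressed genes' fold changes.
#' Two-sided: a draw is as extreme when |null mean| >= |observed mean|; the
#' direction of the observed change is reported as the sign.
#'
#' @param log2_fc named per-gene log2 fold changes (all expressed genes).
#' @param pathway_genes character vector of member gene ids.
#' @param n_draws Monte Carlo draws.
#' @param seed integer seed.
#' @return a `permutation_result` (direction `"two_sided_abs"`).
#' @export
pathway_switch_test <- function(log2_fc, pathway_genes, n_draws = 1e6, seed = 1L) {
  idx <- match(pathway_genes, names(log2_fc))
  if (anyNA(idx)) {
    warning(sprintf("%d pathway genes not in the expressed universe; dropped",
                    sum(is.na(idx))))
    idx <- idx[!is.na(idx)]
  }
  if (!length(idx)) stop("empty pathway after intersection with expressed genes")
  m <- length(idx)
  obs <- mean(log2_fc[idx])
  set.seed(seed)
  n_extreme <- 0L
  chunk <- max(1L, floor(2e6 / m))
  left <- n_draws
  while (left > 0) {
    k <- min(chunk, left)
    draws <- colMeans(matrix(sample(log2_fc, k * m, replace = TRUE), nrow = m))
    n_extreme <- n_extreme + sum(abs(draws) >= abs(obs))
    left <- left - k
  }
  permutation_result(obs, n_draws, n_extreme, "two_sided_abs", seed,
                     sign = sign(obs))
}

#' Convergence diagnostic over a schedule of draw counts
#'
#' Re-runs a permutation test at increasing numbers of draws under one seed
#' (so smaller runs are prefixes of larger ones) and flags stability when
#' successive p-values differ by less than 10% relatively.
#'
#' @param test_closure function(n_draws, seed) returning a
#'   `permutation_result`.
#' @param draw_schedule increasing draw counts (default 1e2..1e6 by decades).
#' @param seed integer seed shared across schedule points.
#' @return data.frame with `n_draws`, `p_value`, `stable` (TRUE from the
#'   first point whose p is within 10% of its predecessor's).
#' @export
convergence_diagnostic <- function(test_closure,
                                   draw_schedule = 10^(2:6), seed = 1L) {
  p <- vapply(draw_schedule,
              function(nd) test_closure(n_draws = nd, seed = seed)$p_value,
              numeric(1))
  rel <- c(NA, abs(diff(p)) / pmax(p[-length(p)], .Machine$double.eps))
  data.frame(n_draws = draw_schedule, p_value = p,
             stable = !is.na(rel) & rel < 0.10)
}
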