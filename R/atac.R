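# Chromatin-accessibility analysis: differential peak counts between
# timepoints, outlier peak removal, TSS distances, CTCF-site scanning and the
# stratified and binned change summaries.

#' Extract peak sequences from a genome
#'
#' @param peaks BED-style data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param genome named `DNAStringSet` (or named character vector).
#' @return character vector of upper-case peak sequences, one per row.
#' @export
peak_sequences <- function(peaks, genome) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing))
    stop(sprintf("chromosome '%s' not in the genome", missing[1L]))
  toupper(as.character(Biostrings::subseq(genome[peaks$chrom],
                                          start = peaks$start + 1L,
                                          end = peaks$end)))
}

#' Count PWM hits in sequences
#'
#' Scores every offset on both strands with the PWM's log2-odds matrix and
#' counts positions scoring at least the effective cutoff
#' `min(cutoff, maximum attainable score)` (so weak matrices still produce
#' hits at their consensus). Overlapping hits are counted individually;
#' windows containing non-ACGT bases never count; sequences shorter than the
#' motif yield 0.
#'
#' @param pwm a [pwm_model()].
#' @param sequences character vector or `DNAStringSet`.
#' @param cutoff nominal log2-odds cutoff (default 10).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return integer vector of hit counts, one per sequence.
#' @export
scan_pwm <- function(pwm, sequences, cutoff = 10, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm_model"))
  if (methods::is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  sequences <- toupper(sequences)
  w <- ncol(pwm$log_odds)
  n <- length(sequences)
  eff_cut <- min(cutoff, pwm$max_score) - 1e-9
  lens <- nchar(sequences)
  hits <- integer(n)
  if (!n || all(lens < w)) return(hits)

  # concatenate with w-1 'N' separators; N scores -Inf so no window crosses
  sep <- strrep("N", w - 1L)
  big <- paste(sequences, collapse = sep)
  code <- utf8ToInt(big)
  lut <- rep(5L, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  idx <- lut[code]
  M <- length(idx) - w + 1L
  if (M < 1L) return(hits)

  score_strand <- function(W) {
    Wn <- rbind(W, -Inf)                      # row 5: non-ACGT
    s <- Wn[idx[seq_len(M)], 1L]
    for (j in 2:w) s <- s + Wn[idx[j:(j + M - 1L)], j]
    s
  }
  W <- pwm$log_odds
  pos <- which(score_strand(W) >= eff_cut)
  if (both_strands) {
    Wrc <- W[4:1, w:1, drop = FALSE]
    pos <- c(pos, which(score_strand(Wrc) >= eff_cut))
  }
  if (length(pos)) {
    starts <- cumsum(c(1L, utils::head(lens, -1L) + (w - 1L)))
    seq_of <- findInterval(pos, starts)
    tab <- tabulate(seq_of, nbins = n)
    hits <- hits + tab
  }
  hits
}

#' Count CTCF binding sites in peaks
#'
#' Predicted sites are PWM hits at a log2-odds cutoff of 10.0, or the maximal
#' score of the weight matrix if that is below 10; both strands are scanned
#' and overlapping hits are counted individually.
#'
#' @param peaks BED-style data.frame.
#' @param genome named `DNAStringSet`.
#' @param ctcf_pwm a [pwm_model()].
#' @param cutoff nominal log2-odds cutoff (default 10).
#' @return integer vector, sites per peak.
#' @export
count_ctcf_sites <- function(peaks, genome, ctcf_pwm, cutoff = 10) {
  scan_pwm(ctcf_pwm, peak_sequences(peaks, genome), cutoff = cutoff)
}

#' Differential accessibility between two timepoints
#'
#' The reported log2 fold change is `log2(mean_b + 1) - log2(mean_a + 1)`
#' over the replicate means of raw counts (the +1 avoids minus infinity);
#' significance comes from [nb_lrt_test()] on the raw replicate counts with
#' Benjamini-Hochberg FDR. Peaks are classed `gained` (log2 fc > 1,
#' FDR < 0.01), `lost` (log2 fc < -1, FDR < 0.01) or `stable`; all-zero
#' peaks are stable and flagged.
#'
#' @param counts peaks x samples integer matrix.
#' @param sample_day numeric day per sample.
#' @param day_a,day_b the two timepoints to compare (a = earlier).
#' @param fdr_cutoff,fc_cutoff classification thresholds (defaults 0.01 and 1).
#' @param dispersion optional fixed NB dispersion passed to [nb_lrt_test()].
#' @return data.frame of class `peak_change`: `name`, `mean_a`, `mean_b`,
#'   `log2_fc`, `p_value`, `fdr`, `change_class`, `flagged`.
#' @export
peak_change <- function(counts, sample_day, day_a, day_b,
                        fdr_cutoff = 0.01, fc_cutoff = 1, dispersion = NULL) {
  sel <- sample_day %in% c(day_a, day_b)
  if (sum(sample_day == day_a) < 2L || sum(sample_day == day_b) < 2L)
    stop("need at least 2 replicates per timepoint")
  sub <- counts[, sel, drop = FALSE]
  grp <- factor(sample_day[sel], levels = c(day_a, day_b))
  mean_a <- rowMeans(sub[, grp == day_a, drop = FALSE])
  mean_b <- rowMeans(sub[, grp == day_b, drop = FALSE])
  fc <- log2(mean_b + 1) - log2(mean_a + 1)
  tst <- nb_lrt_test(sub, grp, dispersion = dispersion)
  cls <- ifelse(fc > fc_cutoff & tst$fdr < fdr_cutoff, "gained",
         ifelse(fc < -fc_cutoff & tst$fdr < fdr_cutoff, "lost", "stable"))
  out <- data.frame(name = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                    mean_a = mean_a, mean_b = mean_b, log2_fc = fc,
                    p_value = tst$p_value, fdr = tst$fdr,
                    change_class = cls, flagged = tst$flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_change", "data.frame")
  out
}

#' Remove the k highest-count peaks as outliers
#'
#' Drops the `k` peaks with the highest total counts over all samples; ties
#' are broken by genomic order (chromosome, then start), so the surviving
#' set does not depend on row order.
#'
#' @param counts peaks x samples matrix.
#' @param peaks BED-style data.frame aligned with `counts` rows.
#' @param k number of peaks to drop (default 10; 0 is the identity).
#' @return list with the filtered `counts`, `peaks` and the dropped `removed`
#'   peak names.
#' @export
remove_top_peaks <- function(counts, peaks, k = 10L) {
  stopifnot(nrow(counts) == nrow(peaks))
  if (k >= nrow(counts)) stop("k must be smaller than the number of peaks")
  if (k == 0L) return(list(counts = counts, peaks = peaks, removed = character(0)))
  total <- rowSums(counts)
  ord <- order(-total, peaks$chrom, peaks$start)
  drop <- ord[seq_len(k)]
  list(counts = counts[-drop, , drop = FALSE],
       peaks = peaks[-drop, , drop = FALSE],
       removed = (rownames(counts) %||% as.character(seq_len(nrow(counts))))[drop])
}

#' Distance from each peak midpoint to the nearest TSS
#'
#' Strand-agnostic: `min over same-chromosome TSS of |midpoint - tss_bp|`
#' with `midpoint = floor((start + end) / 2)`. Peaks on chromosomes without
#' any TSS get NA with a warning.
#'
#' @param peaks BED-style data.frame.
#' @param tss data.frame with `chromosome` and `tss_bp` columns (e.g. the
#'   `genes` table of an annotation).
#' @return numeric vector of distances in bp, one per peak.
#' @export
nearest_tss_distance <- function(peaks, tss) {
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- rep(NA_real_, nrow(peaks))
  tss_by_chr <- split(tss$tss_bp, tss$chromosome)
  for (chr in unique(peaks$chrom)) {
    sel <- peaks$chrom == chr
    pos <- sort(tss_by_chr[[chr]])
    if (is.null(pos)) next
    i <- findInterval(mid[sel], pos)
    lo <- pos[pmax(i, 1L)]
    hi <- pos[pmin(i + 1L, length(pos))]
    out[sel] <- pmin(abs(mid[sel] - lo), abs(hi - mid[sel]))
  }
  if (anyNA(out))
    warning(sprintf("%d peaks on chromosomes without a TSS; distance undefined",
                    sum(is.na(out))))
  out
}

#' 2-D density of accessibility change against TSS distance
#'
#' Normalized 2-D histogram of log10(distance + 1) against log2 fold change,
#' plus the distal-versus-proximal contrast of mean absolute change (split
#' at 1 kb).
#'
#' @param log2_fc per-peak log2 fold changes.
#' @param distance per-peak TSS distances (bp); NA rows are dropped.
#' @param n_bins number of bins per axis (default 25).
#' @return list with `density` (matrix summing to 1), `distance_breaks`
#'   (log10 scale), `fc_breaks`, and `summary` (mean |log2 fc| for proximal
#'   <= 1 kb and distal > 1 kb peaks).
#' @export
change_by_distance_density <- function(log2_fc, distance, n_bins = 25L) {
  keep <- is.finite(log2_fc) & is.finite(distance)
  if (!any(keep)) stop("empty peak table")
  fc <- log2_fc[keep]
  ld <- log10(distance[keep] + 1)
  db <- seq(min(ld), max(ld), length.out = n_bins + 1L)
  fb <- seq(min(fc), max(fc), length.out = n_bins + 1L)
  db[length(db)] <- db[length(db)] + 1e-9
  fb[length(fb)] <- fb[length(fb)] + 1e-9
  di <- findInterval(ld, db, rightmost.closed = TRUE)
  fi <- findInterval(fc, fb, rightmost.closed = TRUE)
  dens <- matrix(0, n_bins, n_bins)
  for (k in seq_along(di)) dens[di[k], fi[k]] <- dens[di[k], fi[k]] + 1
  dens <- dens / sum(dens)
  proximal <- distance[keep] <= 1000
  list(density = dens, distance_breaks = db, fc_breaks = fb,
       summary = c(proximal_mean_abs_fc = mean(abs(fc[proximal])),
                   distal_mean_abs_fc = mean(abs(fc[!proximal]))))
}

#' Accessibility change stratified by CTCF-site count
#'
#' Peaks are split into the groups 0, 1, 2 and >= 3 CTCF sites; for each
#' group the log2 fold changes and the fraction of peaks losing accessibility
#' (log2 fc < -1) are reported. Empty groups are reported as empty, not as
#' errors.
#'
#' @param log2_fc per-peak log2 fold changes.
#' @param ctcf_sites per-peak CTCF-site counts.
#' @return list with `groups` (named list of fold-change vectors) and
#'   `summary` (data.frame: group, n, loss_fraction).
#' @export
ctcf_stratified_change <- function(log2_fc, ctcf_sites) {
  stopifnot(length(log2_fc) == length(ctcf_sites))
  grp <- cut(ctcf_sites, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", "3+"))
  groups <- split(log2_fc, grp)
  summary <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    loss_fraction = vapply(groups, function(v)
      if (length(v)) mean(v < -1) else NA_real_, numeric(1)),
    row.names = NULL)
  list(groups = groups, summary = summary)
}

#' Accessibility change as a function of peak width
#'
#' Binned mean absolute log2 fold change over width quantile bins, plus the
#' Spearman correlation of width with |log2 fc| as the monotone-trend
#' statistic (negative when short regions change more).
#'
#' @param log2_fc per-peak log2 fold changes.
#' @param width_bp per-peak widths.
#' @param n_bins number of width bins (default 6).
#' @return list with `bins` (data.frame: width_lo, width_hi, n,
#'   mean_abs_fc) and `spearman_rho`.
#' @export
change_by_width <- function(log2_fc, width_bp, n_bins = 6L) {
  stopifnot(length(log2_fc) == length(width_bp))
  br <- unique(stats::quantile(width_bp, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(br) < 2L) br <- c(br - 0.5, br + 0.5)   # all widths equal: one bin
  grp <- cut(width_bp, breaks = br, include.lowest = TRUE)
  bins <- data.frame(
    width_lo = utils::head(br, -1L), width_hi = br[-1L],
    n = as.integer(table(grp)),
    mean_abs_fc = as.numeric(tapply(abs(log2_fc), grp, mean)),
    row.names = NULL)
  rho <- if (length(unique(width_bp)) > 1L)
    stats::cor(width_bp, abs(log2_fc), method = "spearman") else NA_real_
  list(bins = bins, spearman_rho = rho)
}
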