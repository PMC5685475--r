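# Accessibility change, outlier peaks, TSS distances, motif scanning and the
# stratified summaries.

test_that("peak change fold changes are definitional with the +1 convention", {
  counts <- rbind(p1 = c(3L, 3L, 3L, 15L, 15L, 15L),
                  p2 = c(10L, 10L, 10L, 10L, 10L, 10L),
                  p3 = rep(0L, 6))
  day <- rep(c(3, 6), each = 3)
  ch <- peak_change(counts, day, 3, 6, dispersion = 0.05)
  expect_equal(ch$log2_fc[1], log2(16) - log2(4))   # mean 3 vs 15 with +1
  expect_equal(ch$log2_fc[2], 0)
  expect_true(ch$flagged[3])
  expect_equal(ch$change_class[3], "stable")
  # identical timepoints: all fold changes zero
  ch0 <- peak_change(counts[, c(1:3, 1:3)], day, 3, 6, dispersion = 0.05)
  expect_equal(ch0$log2_fc, rep(0, 3))
  expect_error(peak_change(counts[, c(1, 4)], c(3, 6), 3, 6), "2 replicates")
})

test_that("null peaks stay FDR-controlled", {
  set.seed(12)
  n <- 1500L
  mu <- 2^runif(n, 5, 8)
  counts <- matrix(rnbinom(n * 6L, mu = rep(mu, 6L), size = 20),
                   nrow = n, dimnames = list(sprintf("p%04d", 1:n), NULL))
  ch <- peak_change(counts, rep(c(3, 6), each = 3), 3, 6)
  expect_lte(sum(ch$change_class != "stable"), 0.01 * n + 3)
})

test_that("top-peak removal drops the k largest totals, order-invariantly", {
  set.seed(4)
  n <- 12L
  counts <- matrix(rpois(n * 3L, 50), n, dimnames = list(sprintf("p%02d", 1:n), NULL))
  counts[3, ] <- 5000L; counts[9, ] <- 4000L
  peaks <- data.frame(chrom = "chr1", start = seq(0, by = 100, length.out = n),
                      end = seq(50, by = 100, length.out = n),
                      name = rownames(counts))
  out <- remove_top_peaks(counts, peaks, k = 10L)
  expect_equal(nrow(out$counts), 2L)
  totals <- rowSums(counts)
  expect_setequal(rownames(out$counts), names(sort(totals)[1:2]))
  # identity at k = 0; error when k exhausts the peaks
  expect_identical(remove_top_peaks(counts, peaks, 0L)$counts, counts)
  expect_error(remove_top_peaks(counts, peaks, 12L), "smaller")
  # permuting rows leaves the surviving set unchanged
  perm <- sample(n)
  out2 <- remove_top_peaks(counts[perm, ], peaks[perm, ], k = 10L)
  expect_setequal(rownames(out2$counts), rownames(out$counts))
})

test_that("nearest TSS distance uses midpoints and the min rule", {
  peaks <- data.frame(chrom = c("chr1", "chr3", "chr2"),
                      start = c(100L, 0L, 10L), end = c(200L, 100L, 20L),
                      name = c("a", "b", "c"))
  tss <- data.frame(chromosome = c("chr1", "chr3", "chr3"),
                    tss_bp = c(150L, 1050L, 5000L))
  expect_warning(d <- nearest_tss_distance(peaks, tss), "without a TSS")
  expect_equal(d[1], 0)        # TSS inside the peak (midpoint 150)
  expect_equal(d[2], 1000)     # midpoint 50: min(|50-1050|, |50-5000|)
  expect_true(is.na(d[3]))
  # ... the min rule: adding a farther TSS never increases any distance
  tss2 <- rbind(tss, data.frame(chromosome = "chr1", tss_bp = 5000L))
  d2 <- suppressWarnings(nearest_tss_distance(peaks, tss2))
  expect_true(all(d2[1:2] <= d[1:2]))
})

test_that("PWM hit counting equals the brute-force oracle on random sequences", {
  set.seed(99)
  lib <- default_motif_library()
  seqs <- vapply(1:100, function(i) random_dna(300), "")
  # plant a few consensus instances so nonzero counts are exercised
  cons <- pwm_consensus(lib[[1]])
  for (i in seq(5, 100, by = 7))
    substr(seqs[i], 50, 50 + nchar(cons) - 1) <- cons
  for (pwm in lib[c(1, 3, 6)]) {
    fast <- scan_pwm(pwm, seqs, cutoff = 10)
    slow <- vapply(seqs, brute_force_pwm_count, integer(1), pwm = pwm, cutoff = 10,
                   USE.NAMES = FALSE)
    expect_identical(unname(fast), slow)
  }
  # reverse-complemented input yields identical counts (strand symmetry)
  rc <- vapply(seqs[1:20], function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, NULL)[[1]]), collapse = "")), "",
    USE.NAMES = FALSE)
  expect_identical(scan_pwm(lib[[1]], rc), scan_pwm(lib[[1]], seqs[1:20]))
  # sequences shorter than the motif yield zero
  expect_identical(scan_pwm(lib[[1]], c("ACGT", cons)), c(0L, 1L))
  # windows containing N never count
  seq_n <- paste0(substr(cons, 1, 10), "N", substr(cons, 12, nchar(cons)))
  expect_identical(scan_pwm(lib[[1]], seq_n), 0L)
})

test_that("distance and width summaries expose the planted couplings", {
  cfg <- simulation_config(n_peaks = 3000L, seed = 83)
  ps <- simulate_peaks(cfg)
  ch <- peak_change(ps$counts, ps$sample_day, 3, 6)
  dist <- nearest_tss_distance(ps$peaks, ps$tss)
  expect_equal(dist, as.numeric(ps$truth$tss_distance))

  dd <- change_by_distance_density(ch$log2_fc, dist)
  expect_equal(sum(dd$density), 1, tolerance = 1e-12)
  expect_gt(dd$summary["distal_mean_abs_fc"], dd$summary["proximal_mean_abs_fc"])
  # identical peaks land in a single occupied cell
  dd1 <- change_by_distance_density(rep(1.5, 40), rep(500, 40), n_bins = 10)
  expect_equal(sum(dd1$density > 0), 1L)
  expect_error(change_by_distance_density(numeric(0), numeric(0)), "empty")

  cw <- change_by_width(ch$log2_fc, ps$truth$width)
  expect_lt(cw$spearman_rho, -0.05)   # short regions change more
  # no width-change coupling: near-zero trend
  set.seed(1)
  cw0 <- change_by_width(rnorm(3000), ps$truth$width)
  expect_lt(abs(cw0$spearman_rho), 0.05)
  # all equal widths: a single bin
  cw1 <- change_by_width(rnorm(10), rep(300, 10))
  expect_equal(nrow(cw1$bins), 1L)
})

test_that("CTCF stratification partitions peaks and orders loss fractions", {
  cfg <- simulation_config(n_peaks = 4000L, seed = 91)
  ps <- simulate_peaks(cfg)
  ch <- peak_change(ps$counts, ps$sample_day, 3, 6)
  ctcf <- count_ctcf_sites(ps$peaks, ps$genome, ps$motifs[[1]])
  strat <- ctcf_stratified_change(ch$log2_fc, ctcf)
  expect_equal(sum(strat$summary$n), nrow(ps$peaks))
  lf <- strat$summary$loss_fraction
  expect_true(all(diff(lf) < 0))   # strictly decreasing across 0/1/2/3+
  # protection disabled: loss fractions are statistically indistinguishable
  cfg0 <- simulation_config(n_peaks = 4000L, seed = 91,
                            motif_beta = c(CTCF_like_synthetic = 0),
                            loss_logit_coefs = c(intercept = -1.2, ctcf = 0,
                                                 log10_distance = 0, width_kb = 0))
  ps0 <- simulate_peaks(cfg0)
  ch0 <- peak_change(ps0$counts, ps0$sample_day, 3, 6)
  ctcf0 <- count_ctcf_sites(ps0$peaks, ps0$genome, ps0$motifs[[1]])
  s0 <- ctcf_stratified_change(ch0$log2_fc, ctcf0)$summary
  tab <- cbind(round(s0$loss_fraction * s0$n), s0$n - round(s0$loss_fraction * s0$n))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.001)
})
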