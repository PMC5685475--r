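# Correlations, PCA over days, fold changes, the NB likelihood-ratio test,
# classification and the chromosome distribution test.

test_that("sample correlations are Pearson with the expected structure", {
  set.seed(2)
  m <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m[, 2] <- m[, 1]          # duplicated sample
  m[, 3] <- -m[, 1]         # negated sample
  r <- sample_correlations(m)
  expect_equal(unname(r[1, 2]), 1)
  expect_equal(unname(r[1, 3]), -1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  m[, 4] <- 7
  expect_error(sample_correlations(m), "s4")
})

test_that("PCA over days: variance fractions, reconstruction, sign and invariance", {
  set.seed(3)
  # rank-1 matrix: all variance on PC1
  g <- rnorm(40); d <- rnorm(13)
  m1 <- outer(g, d)
  dimnames(m1) <- list(sprintf("g%02d", 1:40), paste0("P", 0:12))
  p1 <- pca_timecourse(m1)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-12)
  expect_equal(sum(p1$variance_fraction), 1, tolerance = 1e-9)

  m <- matrix(rnorm(13 * 40), 40, 13,
              dimnames = list(sprintf("g%02d", 1:40), paste0("P", 0:12)))
  p <- pca_timecourse(m)
  # scores x loadings reconstructs the centered day x gene matrix
  xc <- scale(t(m), center = TRUE, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), unclass(xc), tolerance = 1e-8,
               ignore_attr = TRUE)
  # components orthogonal; earliest-day score non-positive
  cp <- crossprod(p$scores)
  expect_equal(cp[upper.tri(cp)], rep(0, sum(upper.tri(cp))), tolerance = 1e-8)
  expect_true(all(p$scores[1, ] <= 1e-12))
  # gene order irrelevant
  p2 <- pca_timecourse(m[sample(40), ])
  expect_equal(p2$scores, p$scores, tolerance = 1e-8)
  expect_error(pca_timecourse(m[, 1:2]), "3 days")
})

test_that("fold changes are post minus pre, excluding day 6", {
  m <- matrix(0, 2, 13, dimnames = list(c("g1", "g2"), paste0("P", 0:12)))
  m[1, ] <- 5                             # constant gene
  m[2, ] <- log2(4) + c(rep(0, 6), 5, rep(log2(188), 6))  # day 6 value must not matter
  fc <- fold_changes(m)
  expect_equal(unname(fc["g1"]), 0)
  expect_equal(unname(fc["g2"]), log2(188))   # a 188-fold switch ~ 7.55 log2 units
  expect_equal(unname(fold_changes(m, pre_days = 7:12, post_days = 0:5)["g2"]),
               -log2(188))                    # swapping windows negates
  expect_error(fold_changes(m, pre_days = 0:6, post_days = 6:12), "overlap")
})

test_that("NB LRT matches a direct grid-search MLE oracle and the Poisson limit", {
  set.seed(7)
  n1 <- 3L; n2 <- 6L
  y <- c(rnbinom(n1, mu = 10, size = 20), rnbinom(n2, mu = 160, size = 20))
  counts <- matrix(y, 1, dimnames = list("g1", NULL))
  grp <- factor(rep(c("a", "b"), c(n1, n2)))
  res <- nb_lrt_test(counts, grp, dispersion = 0.05, lib_sizes = rep(1, n1 + n2))
  expect_lt(res$p_value, 1e-4)

  # oracle: profile the NB log-likelihood by 1-D optimization per model
  off <- rep(0, n1 + n2)
  ll_mean <- function(idx) {
    f <- function(b) sum(dnbinom(y[idx], size = 20, mu = exp(b + off[idx]), log = TRUE))
    optimize(f, c(-30, 10), maximum = TRUE, tol = 1e-10)$objective
  }
  stat_oracle <- 2 * ((ll_mean(1:n1) + ll_mean(n1 + 1:n2)) - ll_mean(1:(n1 + n2)))
  expect_equal(res$lrt_stat, stat_oracle, tolerance = 1e-5)

  # Poisson limit: dispersion -> 0 reproduces the exact Poisson LRT statistic
  pois_ll <- function(idx) {
    lam <- sum(y[idx]) / sum(exp(off[idx]))
    sum(dpois(y[idx], lam * exp(off[idx]), log = TRUE))
  }
  stat_pois <- 2 * ((pois_ll(1:n1) + pois_ll(n1 + 1:n2)) - pois_ll(1:(n1 + n2)))
  res0 <- nb_lrt_test(counts, grp, dispersion = 1e-12, lib_sizes = rep(1, n1 + n2))
  expect_equal(res0$lrt_stat, stat_pois, tolerance = 1e-6)

  # all-zero gene: p = 1, flagged
  zz <- rbind(gz = rep(0L, 9), g1 = rep(1L, 9))
  rz <- nb_lrt_test(zz, factor(rep(c("a", "b"), c(3, 6))))
  expect_equal(rz$p_value[1], 1)
  expect_true(rz$flagged[1])
})

test_that("NB LRT type-I error is close to nominal under the null", {
  set.seed(17)
  n_genes <- 2000L
  mu <- rep(2^runif(n_genes, 3, 9), each = 12L)
  counts <- matrix(rnbinom(n_genes * 12L, mu = mu, size = 1 / 0.05),
                   nrow = n_genes, byrow = TRUE,
                   dimnames = list(sprintf("g%04d", 1:n_genes), NULL))
  grp <- factor(rep(c("a", "b"), each = 6L))
  res <- nb_lrt_test(counts, grp)
  t1 <- mean(res$p_value < 0.05)
  # 0.05 plus/minus binomial MC error and chi-square approximation slack
  expect_gt(t1, 0.03)
  expect_lt(t1, 0.07)
})

test_that("NB LRT agrees with an established exact-test ranking on a small fixture", {
  skip_if_not_installed("edgeR")
  set.seed(23)
  n_genes <- 300L
  eff <- c(rep(2, 30), rep(0, 270))
  mu_a <- 2^runif(n_genes, 4, 8)
  mu <- cbind(matrix(mu_a, n_genes, 4), matrix(mu_a * 2^eff, n_genes, 4))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 20), n_genes,
                   dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
  grp <- factor(rep(c("a", "b"), each = 4L))
  mine <- nb_lrt_test(counts, grp)
  dge <- edgeR::DGEList(counts = counts, group = grp)
  dge <- edgeR::estimateDisp(dge)
  et <- edgeR::exactTest(dge)
  expect_gt(cor(-log10(mine$p_value + 1e-300), -log10(et$table$PValue + 1e-300),
                method = "spearman"), 0.9)
})

test_that("classification applies the fold-change and FDR rules", {
  fc <- c(a = 1.5, b = 1.5, c = 0.005, d = -1.2, e = 0.5, f = 2.5)
  tst <- data.frame(gene_id = names(fc), lrt_stat = 1, p_value = 1,
                    fdr = c(0.01, 0.2, 0.9, 0.001, 0.01, 0.001))
  sw <- classify(fc, tst)
  expect_equal(sw$class, c("switch_on", "other", "constant", "switch_off",
                           "other", "switch_on"))
  expect_equal(sw$strong, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # idempotent and a function of (fc, fdr) only
  sw2 <- classify(setNames(sw$log2_fc, sw$gene_id), sw)
  expect_equal(sw2$class, sw$class)
})

test_that("normalized time courses sit at zero in the reference window", {
  cfg <- test_config(seed = 19)
  sim <- simulate_expression(cfg)
  prep <- prep_expression(sim$counts, seed = 2)
  lg <- prep$log2_expr
  truth <- sim$truth[match(rownames(lg$values), sim$truth$gene_id), ]

  const <- truth$gene_id[truth$class == "constant"]
  curve_c <- normalized_timecourse(lg, const)
  expect_lt(max(abs(curve_c)), 0.25)

  on_genes <- truth$gene_id[truth$class == "switch_on"]
  curve_on <- normalized_timecourse(lg, on_genes, reference = "pre")
  pre_mean <- mean(curve_on[1:6]); post_mean <- mean(curve_on[8:13])
  true_eff <- mean(truth$effect_log2[truth$class == "switch_on"])
  expect_lt(abs(pre_mean), 0.2)
  expect_lt(abs(post_mean - true_eff), 0.75)
  # post reference flips which plateau is at zero
  curve_on2 <- normalized_timecourse(lg, on_genes, reference = "post")
  expect_lt(abs(mean(curve_on2[8:13])), 0.2)
  expect_error(normalized_timecourse(lg, character(0)), "empty")
})

test_that("chromosome distribution test is calibrated and detects concentration", {
  set.seed(5)
  n <- 10000L
  ann <- list(genes = data.frame(
    gene_id = sprintf("g%05d", 1:n),
    chromosome = sample(paste0("chr", 1:20), n, replace = TRUE),
    tss_bp = seq_len(n), strand = "+", is_tf = FALSE, is_cone_specific = FALSE))
  all_genes <- ann$genes$gene_id

  # switch sets drawn uniformly from a large universe give uniform p-values
  # (the sampling fraction is kept small so the finite-population correction
  # is negligible)
  ps <- replicate(200, {
    chromosome_distribution_test(sample(all_genes, 200), all_genes, ann)$p.value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  # all switch genes on one chromosome: overwhelming evidence
  one_chr <- all_genes[ann$genes$chromosome == "chr1"]
  p_conc <- chromosome_distribution_test(one_chr, all_genes, ann)$p.value
  expect_lt(p_conc, 1e-6)

  # observed proportional to expected: statistic 0
  res0 <- chromosome_distribution_test(all_genes, all_genes, ann)
  expect_equal(res0$statistic, 0, tolerance = 1e-9)
  expect_equal(res0$p.value, 1)
  expect_error(chromosome_distribution_test(character(0), all_genes, ann), "empty")
})
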