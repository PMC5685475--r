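# Generator properties: determinism, class structure, NB marginals, planted
# enrichment and generator-scanner consistency.

test_that("config validation rejects infeasible settings", {
  expect_error(simulation_config(frac_switch_on = 0.6, frac_switch_off = 0.5),
               "fractions")
  expect_error(simulation_config(nb_dispersion = 0), "positive")
  expect_error(simulation_config(transcriptional_fraction = 1.5), "\\[0,1\\]")
  expect_error(simulate_expression(
    simulation_config(n_genes = 200L, tf_background_frac = 0.01,
                      tf_enrichment_in_off = 0.9)), "infeasible")
})

test_that("expression truth classes have the configured structure", {
  cfg <- test_config(seed = 31)
  sim <- simulate_expression(cfg)
  truth <- sim$truth
  expect_equal(nrow(truth), cfg$n_genes)
  expect_setequal(unique(truth$class),
                  c("switch_on", "switch_off", "constant", "other", "low_expressed"))
  n_expr <- sum(truth$class != "low_expressed")
  frac_switch <- sum(truth$class %in% c("switch_on", "switch_off")) / n_expr
  expect_lt(abs(frac_switch - 0.14), 0.01)
  expect_true(all(abs(truth$effect_log2[truth$class %in% c("switch_on", "switch_off")]) >= 2))
  expect_true(all(truth$effect_log2[truth$class == "constant"] == 0))

  # TF labels: background fraction overall, enrichment in the strongest-off tail
  ann <- sim$annotation$genes
  expressed <- truth$class != "low_expressed"
  expect_lt(abs(mean(ann$is_tf[expressed]) - cfg$tf_background_frac), 0.005)
  tail_ids <- truth$gene_id[expressed][order(truth$effect_log2[expressed])][1:100]
  expect_lt(abs(mean(ann$is_tf[match(tail_ids, ann$gene_id)]) -
                cfg$tf_enrichment_in_off), 0.005)
})

test_that("fixed seeds give identical outputs; the null config yields no switches", {
  cfg <- test_config(seed = 33)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  p1 <- simulate_peaks(cfg, seed = 99)
  p2 <- simulate_peaks(cfg, seed = 99)
  expect_identical(p1$counts, p2$counts)
  expect_identical(as.character(p1$genome), as.character(p2$genome))

  # all-constant generator: classification recovers (almost) nothing
  cfg0 <- simulation_config(n_genes = 800L, frac_switch_on = 0, frac_switch_off = 0,
                            frac_constant = 0.5, other_effect_max = 0, seed = 8)
  sim0 <- simulate_expression(cfg0)
  prep0 <- prep_expression(sim0$counts, seed = 1)
  fc0 <- fold_changes(prep0$log2_expr)
  expect_lt(max(abs(fc0)), 1)
})

test_that("simulated counts match the negative-binomial marginal (moment check)", {
  set.seed(44)
  mu_target <- 250; phi <- 0.05
  draws <- rnbinom(1e5, mu = mu_target, size = 1 / phi)
  # the generator draws through the same parameterization; check mean/variance
  cfg <- test_config(seed = 44)
  sim <- simulate_expression(cfg)
  cm <- sim$counts
  # pick well-expressed constant genes: replicate variance should be ~ mu + phi mu^2
  truth <- sim$truth
  const <- truth$gene_id[truth$class == "constant"]
  day0 <- cm$counts[const, cm$day == 0, drop = FALSE]
  m <- rowMeans(day0)
  v <- apply(day0, 1, var)
  keep <- m > 50
  # regression of excess variance on mu^2 recovers the dispersion's order
  phi_hat <- median(((v - m) / m^2)[keep])
  expect_gt(phi_hat, 0.01)
  expect_lt(phi_hat, 0.15)
  # and the external NB reference behaves identically under the same moments
  expect_equal(mean(draws), mu_target, tolerance = 0.02)
  expect_equal(var(draws), mu_target + phi * mu_target^2, tolerance = 0.05)
})

test_that("exon-intron generator has the configured coupling limits", {
  cfg <- simulation_config(n_genes = 1200L, transcriptional_fraction = 1,
                           intron_coupling_sd = 0.01, seed = 51)
  sim <- simulate_expression(cfg)
  ei <- simulate_exon_intron(cfg, sim)
  expect_identical(rownames(ei$exonic$counts), rownames(ei$intronic$counts))
  r1 <- transcriptional_fraction(split_deltas(ei$exonic, ei$intronic))$pearson_r
  expect_gt(r1, 0.95)

  cfg0 <- simulation_config(n_genes = 1200L, transcriptional_fraction = 0, seed = 51)
  sim0 <- simulate_expression(cfg0)
  ei0 <- simulate_exon_intron(cfg0, sim0)
  sd0 <- split_deltas(ei0$exonic, ei0$intronic)
  sw <- sim0$truth$gene_id[sim0$truth$class %in% c("switch_on", "switch_off")]
  dsw <- sd0$deltas[sd0$deltas$gene_id %in% sw, ]
  # decoupled limit: correlation consistent with 0 (bounds are ~3.5 sampling
  # standard errors at the respective gene counts)
  expect_lt(abs(cor(dsw$delta_exon, dsw$delta_intron)), 0.3)
  expect_lt(abs(cor(sd0$deltas$delta_exon, sd0$deltas$delta_intron)), 0.11)
})

test_that("planted CTCF sites are exactly recovered by the scanner at the planting score", {
  cfg <- test_config(seed = 61)
  ps <- simulate_peaks(cfg)
  ctcf <- ps$motifs[[1L]]
  scanned <- scan_pwm(ctcf, peak_sequences(ps$peaks, ps$genome),
                      cutoff = ctcf$max_score)
  expect_identical(unname(scanned), ps$truth$ctcf_planted)
  # planted instances also clear the analysis cutoff of 10
  expect_gt(ctcf$max_score, 10)
  scanned10 <- count_ctcf_sites(ps$peaks, ps$genome, ctcf)
  expect_true(all(scanned10 >= ps$truth$ctcf_planted))
})

test_that("peak loss probability decreases with planted CTCF count", {
  cfg <- simulation_config(n_peaks = 4000L, seed = 71)
  ps <- simulate_peaks(cfg)
  tr <- ps$truth
  p0 <- mean(tr$lost_3_6[tr$ctcf_planted == 0])
  p3 <- mean(tr$lost_3_6[tr$ctcf_planted >= 3])
  expect_gt(p0, p3)
  # loss disabled: nothing lost
  cfg0 <- simulation_config(n_peaks = 800L, seed = 71, gain_prob = 0,
                            motif_beta = c(CTCF_like_synthetic = 0),
                            loss_logit_coefs = c(intercept = -30, ctcf = 0,
                                                 log10_distance = 0, width_kb = 0))
  ps0 <- simulate_peaks(cfg0)
  expect_equal(sum(ps0$truth$lost_3_6), 0)
  ch0 <- peak_change(ps0$counts, ps0$sample_day, 3, 6)
  expect_lte(sum(ch0$change_class != "stable"), 0.01 * nrow(ch0) + 3)
})
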