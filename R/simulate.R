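# Synthetic-data module: generates every input the pipeline consumes, with
# known ground truth, emulating the statistical structure of a 13-day cone
# developmental time course (expression), its exonic/intronic split, and a
# three-timepoint ATAC peak-count experiment with planted CTCF sites.

#' Simulation configuration
#'
#' Validated parameter set for the synthetic-data generators. Defaults encode
#' the study conditions the pipeline is designed for: postnatal days 0-12 with
#' three replicates each, an abrupt expression switch at day 6 affecting 14%
#' of expressed genes, transcription factors at 6% background enriched to 23%
#' among the strongest switch-off genes, exon-intron coupling calibrated so
#' the recovered exon-intron correlation is about 0.84, and accessibility
#' peaks whose probability of loss between day 3 and day 6 decreases with
#' planted CTCF-site count and width and increases with TSS distance.
#'
#' @param n_genes total genes simulated (expressed + low-expression mode).
#' @param days integer vector of postnatal days.
#' @param n_replicates replicates per day.
#' @param switch_day day at which switch genes jump (logistic midpoint).
#' @param logistic_scale logistic time scale of the switch, in days.
#' @param frac_switch_on,frac_switch_off,frac_constant fractions of *expressed*
#'   genes per truth class (remainder is the weakly drifting "other" class).
#' @param frac_low fraction of all genes placed in a low-expression mode below
#'   the intended detection threshold (creates the bimodal abundance structure
#'   the threshold-selection step assumes).
#' @param effect_size_log2 length-2 vector: range of |log2 effect| for switch genes.
#' @param other_effect_max maximum |log2 effect| of "other" genes.
#' @param tf_background_frac fraction of expressed genes labelled TF overall.
#' @param tf_enrichment_in_off target TF fraction in the strongest-off tail.
#' @param tf_tail_size size of the strongest-off tail used for enrichment.
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param library_size_mean,library_size_cv lognormal library-size model.
#' @param transcriptional_fraction share of genes whose intronic change tracks
#'   their exonic change (calibrated default 0.73; see the methods vignette).
#' @param intron_ratio intronic/exonic baseline abundance ratio.
#' @param intron_coupling_sd extra log2 noise on the intronic effect of
#'   transcriptionally regulated genes.
#' @param n_peaks number of accessibility peaks.
#' @param peak_frac_proximal fraction of promoter-like (wide, TSS-proximal) peaks.
#' @param proximal_width,distal_width length-2 (mean, sd) of peak widths in bp.
#' @param ctcf_lambda Poisson mean of planted CTCF sites per peak.
#' @param loss_logit_coefs named vector (intercept, ctcf, log10_distance,
#'   width_kb) of the day3->day6 loss logit; distance enters as
#'   log10(distance+1) - 3 and width as (width - 500)/300, so the intercept is
#'   the logit for a 500-bp peak 1 kb from its TSS with no CTCF sites.
#' @param gain_prob probability a (non-lost) peak gains accessibility day3->day6.
#' @param late_change_prob probability of any change day6->day10.
#' @param atac_effect length-2 range of |log2| accessibility change for
#'   lost/gained peaks.
#' @param peak_base_log2 length-2 (mean, sd) of baseline log2 peak counts.
#' @param atac_dispersion NB dispersion of peak counts.
#' @param motif_beta named numeric, direct per-planted-site log2 effect on the
#'   day-6 accessibility of each motif; the default plants a stabilising
#'   +0.25 log2 per CTCF site on top of the protective loss-logit effect.
#' @param seed default integer seed for the generators.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000L,
                              days = 0:12,
                              n_replicates = 3L,
                              switch_day = 6,
                              logistic_scale = 0.25,
                              frac_switch_on = 0.045,
                              frac_switch_off = 0.095,
                              frac_constant = 0.20,
                              frac_low = 0.20,
                              effect_size_log2 = c(2, 6),
                              other_effect_max = 0.9,
                              tf_background_frac = 0.06,
                              tf_enrichment_in_off = 0.23,
                              tf_tail_size = 100L,
                              nb_dispersion = 0.05,
                              library_size_mean = 5e6,
                              library_size_cv = 0.15,
                              transcriptional_fraction = 0.73,
                              intron_ratio = 0.125,
                              intron_coupling_sd = 0.15,
                              n_peaks = 5000L,
                              peak_frac_proximal = 0.3,
                              proximal_width = c(900, 150),
                              distal_width = c(350, 80),
                              ctcf_lambda = 0.8,
                              loss_logit_coefs = c(intercept = -0.8, ctcf = -1.0,
                                                   log10_distance = 0.6, width_kb = -0.5),
                              gain_prob = 0.02,
                              late_change_prob = 0.001,
                              atac_effect = c(1.5, 3),
                              peak_base_log2 = c(6.5, 0.8),
                              atac_dispersion = 0.05,
                              motif_beta = c(CTCF_like_synthetic = 0.25),
                              seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_switch_on, frac_switch_off, frac_constant)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("class fractions must lie in [0,1] and sum to at most 1")
  if (frac_low < 0 || frac_low >= 1) stop("frac_low must lie in [0,1)")
  if (nb_dispersion <= 0 || atac_dispersion <= 0) stop("dispersions must be positive")
  if (transcriptional_fraction < 0 || transcriptional_fraction > 1)
    stop("transcriptional_fraction must lie in [0,1]")
  if (length(days) < 3L) stop("need at least 3 days")
  if (tf_enrichment_in_off < 0 || tf_enrichment_in_off > 1)
    stop("tf_enrichment_in_off must lie in [0,1]")
  stopifnot(length(effect_size_log2) == 2L, effect_size_log2[1] > 0,
            diff(effect_size_log2) >= 0)
  class(cfg) <- "simulation_config"
  cfg
}

# internal: logistic switch shape over days, in [0,1]
switch_shape <- function(days, switch_day, scale) {
  stats::plogis((days - switch_day) / scale)
}

# internal: lognormal library sizes around a target mean
draw_library_sizes <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# internal: NB count matrix (genes x samples) from a per-gene-per-day mean
# RPKM matrix, gene lengths and per-sample library sizes
draw_nb_counts <- function(mean_rpkm, gene_length, lib_sizes, sample_days,
                           days, dispersion) {
  day_idx <- match(sample_days, days)
  mu <- mean_rpkm[, day_idx, drop = FALSE] *
    (gene_length / 1e9) %o% lib_sizes
  m <- matrix(as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)),
              nrow = nrow(mu))
  dimnames(m) <- dimnames(mu)
  m
}

#' Simulate a developmental expression time course with ground truth
#'
#' Counts are negative binomial around a per-gene mean-RPKM time course:
#' switch genes jump by their log2 effect at `switch_day` with logistic
#' sharpness well under one day; constant genes are flat; "other" genes drift
#' weakly; a low-expression mode sits below the intended detection threshold.
#' TF labels hit `tf_background_frac` overall and `tf_enrichment_in_off` in
#' the strongest-off tail. Pathway sets include a switch-on biased
#' ("phototransduction_like"), a switch-off biased ("axon_guidance_like") and
#' several null sets; 41 switch-on genes are flagged cone-specific.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (default `config$seed`).
#' @return list of class `expression_sim` with elements `counts`
#'   ([count_matrix()]), `annotation` (list `genes`, `pathways`), `truth`
#'   (data.frame: gene_id, class, effect_log2, is_transcriptional,
#'   baseline_log2_rpkm) and `mean_rpkm` (genes x days true means).
#' @export
simulate_expression <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n_genes
  n_low <- round(config$frac_low * n)
  n_expr <- n - n_low
  n_on <- round(config$frac_switch_on * n_expr)
  n_off <- round(config$frac_switch_off * n_expr)
  n_const <- round(config$frac_constant * n_expr)
  n_other <- n_expr - n_on - n_off - n_const
  if (n_other < 0) stop("class fractions exceed the expressed-gene pool")

  gene_id <- sprintf("gene%05d", seq_len(n))
  classes <- c(rep("switch_on", n_on), rep("switch_off", n_off),
               rep("constant", n_const), rep("other", n_other),
               rep("low_expressed", n_low))
  classes <- sample(classes)                   # random gene order
  expressed <- classes != "low_expressed"

  effect <- numeric(n)
  effect[classes == "switch_on"] <- stats::runif(n_on, config$effect_size_log2[1],
                                                 config$effect_size_log2[2])
  effect[classes == "switch_off"] <- -stats::runif(n_off, config$effect_size_log2[1],
                                                   config$effect_size_log2[2])
  effect[classes == "other"] <- stats::runif(n_other, -config$other_effect_max,
                                             config$other_effect_max)

  # the expressed-phase level is drawn from the normal abundance range: for
  # switch-on genes that is the post-switch plateau (baseline = level - effect),
  # so strong switchers never dominate the library of either phase
  level <- ifelse(expressed, stats::rnorm(n, 3.5, 1.3), stats::rnorm(n, -6, 0.8))
  baseline <- ifelse(classes == "switch_on", level - effect, level)
  gene_length <- pmax(200L, round(10^stats::rnorm(n, 3.35, 0.25)))

  shape <- switch_shape(config$days, config$switch_day, config$logistic_scale)
  mean_log2 <- outer(baseline, rep(1, length(config$days))) + effect %o% shape
  mean_rpkm <- 2^mean_log2
  # self-consistent scale: expected library equals the nominal library size
  scale_f <- 1e9 / mean(colSums(mean_rpkm * gene_length))
  mean_rpkm <- mean_rpkm * scale_f
  dimnames(mean_rpkm) <- list(gene_id, paste0("P", config$days))

  sample_days <- rep(config$days, each = config$n_replicates)
  sample_rep <- rep(seq_len(config$n_replicates), times = length(config$days))
  sample_id <- sprintf("P%02d_r%d", sample_days, sample_rep)
  libs <- draw_library_sizes(length(sample_id), config$library_size_mean,
                             config$library_size_cv)
  counts <- draw_nb_counts(mean_rpkm, gene_length, libs, sample_days,
                           config$days, config$nb_dispersion)
  dimnames(counts) <- list(gene_id, sample_id)
  cm <- count_matrix(counts, day = sample_days, replicate = sample_rep,
                     gene_length = gene_length)

  # TF labels: preferential labelling in the strongest-off tail, remainder
  # filled at random to reach the global background fraction
  rk <- order(effect + stats::runif(n, -1e-9, 1e-9))  # ascending; jitter breaks ties
  rk <- rk[expressed[rk]]
  tail_n <- min(config$tf_tail_size, length(rk))
  n_tf_tail <- round(config$tf_enrichment_in_off * tail_n)
  n_tf_total <- round(config$tf_background_frac * n_expr)
  if (n_tf_total < n_tf_tail)
    stop("infeasible TF enrichment: tail demands more TFs than the global fraction allows")
  if (n_tf_total - n_tf_tail > length(rk) - tail_n)
    stop("infeasible TF enrichment: not enough non-tail genes")
  is_tf <- logical(n)
  is_tf[sample(rk[seq_len(tail_n)], n_tf_tail)] <- TRUE
  is_tf[sample(rk[-seq_len(tail_n)], n_tf_total - n_tf_tail)] <- TRUE

  on_genes <- gene_id[classes == "switch_on"]
  off_genes <- gene_id[classes == "switch_off"]
  expr_genes <- gene_id[expressed]
  is_cone <- logical(n)
  cone_set <- sample(on_genes, min(41L, length(on_genes)))
  is_cone[match(cone_set, gene_id)] <- TRUE
  pathways <- list(
    phototransduction_like = sample(on_genes, min(30L, length(on_genes))),
    axon_guidance_like = sample(off_genes, min(40L, length(off_genes))))
  for (k in 1:5)
    pathways[[paste0("null_set_", k)]] <- sample(expr_genes, sample(20:60, 1L))

  annotation <- list(
    genes = data.frame(
      gene_id = gene_id,
      chromosome = sample(paste0("chr", 1:19), n, replace = TRUE),
      tss_bp = sample.int(1e8, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      is_tf = is_tf,
      is_cone_specific = is_cone,
      stringsAsFactors = FALSE),
    pathways = pathways)

  truth <- data.frame(
    gene_id = gene_id, class = classes, effect_log2 = effect,
    is_transcriptional = stats::runif(n) < config$transcriptional_fraction,
    baseline_log2_rpkm = baseline, stringsAsFactors = FALSE)

  structure(list(counts = cm, annotation = annotation, truth = truth,
                 mean_rpkm = mean_rpkm, config = config),
            class = "expression_sim")
}

#' Simulate matched exonic and intronic count matrices
#'
#' Exonic counts follow the same per-gene time course as
#' [simulate_expression()]; intronic counts have the same change for
#' transcriptionally regulated genes (truth flag `is_transcriptional`, plus
#' small coupling noise) and a flat time course for the post-transcriptional
#' remainder, at `intron_ratio` of the exonic abundance.
#'
#' @param config a [simulation_config()].
#' @param sim an `expression_sim` from [simulate_expression()].
#' @param seed integer seed.
#' @return list with `exonic` and `intronic` [count_matrix()] objects sharing
#'   gene and sample ids.
#' @export
simulate_exon_intron <- function(config, sim, seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"), inherits(sim, "expression_sim"))
  set.seed(seed)
  truth <- sim$truth
  n <- nrow(truth)
  days <- config$days
  shape <- switch_shape(days, config$switch_day, config$logistic_scale)

  intron_effect <- ifelse(
    truth$is_transcriptional,
    truth$effect_log2 + stats::rnorm(n, 0, config$intron_coupling_sd),
    0)
  exon_log2 <- outer(truth$baseline_log2_rpkm, rep(1, length(days))) +
    truth$effect_log2 %o% shape
  intron_log2 <- outer(truth$baseline_log2_rpkm + log2(config$intron_ratio),
                       rep(1, length(days))) + intron_effect %o% shape

  gene_length <- sim$counts$gene_length
  sample_days <- sim$counts$day
  make <- function(mean_log2) {
    r <- 2^mean_log2
    r <- r * (1e9 / mean(colSums(r * gene_length)))
    dimnames(r) <- list(truth$gene_id, paste0("P", days))
    libs <- draw_library_sizes(ncol(sim$counts$counts), config$library_size_mean,
                               config$library_size_cv)
    m <- draw_nb_counts(r, gene_length, libs, sample_days, days, config$nb_dispersion)
    dimnames(m) <- dimnames(sim$counts$counts)
    count_matrix(m, day = sample_days, replicate = sim$counts$replicate,
                 gene_length = gene_length)
  }
  list(exonic = make(exon_log2), intronic = make(intron_log2))
}

# internal: reverse complement of a plain character DNA string
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, NULL), function(x) paste(rev(x), collapse = ""), ""))
}

#' Simulate ATAC peaks: genome, intervals, counts and truth
#'
#' Emits one contig per peak (flank + peak body + flank) with CTCF-like motif
#' instances planted at the matrix consensus (so their score equals the
#' maximum attainable log2-odds and they are exactly recoverable by
#' [scan_pwm()] at that score). Each contig carries one annotated TSS at the
#' peak's planted distance from the peak midpoint. The probability that a
#' peak loses accessibility between day 3 and day 6 follows the logistic
#' model in `config$loss_logit_coefs` (decreasing in CTCF count and width,
#' increasing in TSS distance); changes between day 6 and day 10 are rare.
#' Counts per peak, timepoint and replicate are negative binomial.
#'
#' @param config a [simulation_config()].
#' @param motifs motif library (list of [pwm_model()]); the first entry is
#'   planted as the CTCF-like motif.
#' @param seed integer seed.
#' @return list of class `peak_sim` with `genome` (DNAStringSet), `peaks`
#'   (BED-style data.frame), `counts` (peaks x samples), `sample_day`,
#'   `sample_replicate`, `tss` (annotation data.frame), `truth` (data.frame
#'   with planted CTCF counts, distances, loss/gain labels) and `motifs`.
#' @export
simulate_peaks <- function(config, motifs = default_motif_library(),
                           seed = config$seed + 2L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n_peaks
  ctcf <- motifs[[1L]]
  cons <- pwm_consensus(ctcf)
  w_motif <- nchar(cons)

  proximal <- stats::runif(n) < config$peak_frac_proximal
  width <- ifelse(proximal,
                  pmax(300, round(stats::rnorm(n, config$proximal_width[1], config$proximal_width[2]))),
                  pmax(150, round(stats::rnorm(n, config$distal_width[1], config$distal_width[2]))))
  if (any(width < w_motif)) stop("planted motif longer than peak")
  distance <- ifelse(proximal,
                     round(abs(stats::rnorm(n, 0, 300))),
                     round(10^stats::runif(n, 3.05, 4.6)))
  ctcf_target <- stats::rpois(n, config$ctcf_lambda)

  flank <- 60L
  contig_len <- width + 2L * flank
  name <- sprintf("peak%05d", seq_len(n))

  # background sequence, then plant consensus instances inside the peak body
  bases <- c("A", "C", "G", "T")
  all_bases <- sample(bases, sum(contig_len), replace = TRUE)
  seqs <- vapply(split(all_bases, rep.int(seq_len(n), contig_len)),
                 paste, "", collapse = "")
  names(seqs) <- name
  cons_rc <- revcomp_chr(cons)
  ctcf_planted <- integer(n)
  for (i in which(ctcf_target > 0L)) {
    placed <- integer(0)
    for (k in seq_len(ctcf_target[i])) {
      for (try in 1:50) {
        pos <- sample.int(width[i] - w_motif + 1L, 1L) + flank  # 1-based in contig
        if (!length(placed) || all(abs(placed - pos) >= w_motif)) {
          placed <- c(placed, pos)
          inst <- if (stats::runif(1) < 0.5) cons else cons_rc
          substr(seqs[i], pos, pos + w_motif - 1L) <- inst
          break
        }
      }
    }
    ctcf_planted[i] <- length(placed)
  }

  peaks <- data.frame(chrom = name, start = flank, end = flank + width,
                      name = name, stringsAsFactors = FALSE)
  mid <- floor((peaks$start + peaks$end) / 2)
  tss <- data.frame(gene_id = sprintf("tss%05d", seq_len(n)),
                    chromosome = name, tss_bp = mid + distance,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    stringsAsFactors = FALSE)

  cf <- config$loss_logit_coefs
  logit <- cf[["intercept"]] + cf[["ctcf"]] * ctcf_planted +
    cf[["log10_distance"]] * (log10(distance + 1) - 3) +
    cf[["width_kb"]] * (width - 500) / 300
  p_loss <- stats::plogis(logit)
  lost36 <- stats::runif(n) < p_loss
  gained36 <- !lost36 & stats::runif(n) < config$gain_prob
  late <- stats::runif(n) < config$late_change_prob
  lost610 <- late & stats::runif(n) < 0.5
  gained610 <- late & !lost610

  eff <- stats::runif(n, config$atac_effect[1], config$atac_effect[2])
  beta <- rep(0, length(motifs))
  names(beta) <- names(motifs)
  if (!is.null(config$motif_beta))
    beta[names(config$motif_beta)] <- config$motif_beta
  m6 <- 2^(ifelse(lost36, -eff, ifelse(gained36, eff, 0)) + beta[1L] * ctcf_planted)
  m10 <- m6 * 2^(ifelse(lost610, -eff, ifelse(gained610, eff, 0)))

  base <- 2^stats::rnorm(n, config$peak_base_log2[1], config$peak_base_log2[2])
  tp <- c(3L, 6L, 10L)
  sample_day <- rep(tp, each = 3L)
  sample_rep <- rep(1:3, times = 3L)
  sf <- draw_library_sizes(length(sample_day), 1, config$library_size_cv)
  mult <- cbind(rep(1, n), m6, m10)[, match(sample_day, tp)]
  mu <- base * mult * rep(sf, each = n)
  counts <- matrix(as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / config$atac_dispersion)),
                   nrow = n, dimnames = list(name, sprintf("P%02d_r%d", sample_day, sample_rep)))

  truth <- data.frame(name = name, width = width, proximal = proximal,
                      tss_distance = distance, ctcf_planted = ctcf_planted,
                      p_loss = p_loss, lost_3_6 = lost36, gained_3_6 = gained36,
                      lost_6_10 = lost610, gained_6_10 = gained610,
                      effect_log2 = eff, stringsAsFactors = FALSE)

  structure(list(genome = Biostrings::DNAStringSet(seqs), peaks = peaks,
                 counts = counts, sample_day = sample_day,
                 sample_replicate = sample_rep, tss = tss, truth = truth,
                 motifs = motifs, config = config),
            class = "peak_sim")
}
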