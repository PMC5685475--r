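# Single entry point chaining all stages over one output directory, with a
# global seed fanned out to per-stage child seeds (see stage_seed()), staged
# TSV outputs, and a run manifest (config hash, seed, per-stage wall time).

pipeline_stages <- c("simulate", "prep", "switch", "enrich", "eisa", "atac", "motifs")

# internal: stable hash of a config (md5 of its canonical YAML rendering)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Read a simulation/pipeline config from YAML
#'
#' Any field of [simulation_config()] may be set; unset fields keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a [simulation_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$loss_logit_coefs)) vals$loss_logit_coefs <- unlist(vals$loss_logit_coefs)
  do.call(simulation_config, vals)
}

# internal
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, expression prep, switch analysis, enrichment,
#' exon-intron split analysis, accessibility analysis and motif regression in
#' order, writing each stage's tables under `out_dir` and returning a run
#' manifest. Stages are skippable via `stages`; a skipped upstream stage must
#' have been run into the same `out_dir` before (the in-memory state is
#' rebuilt from the simulation stage, which is deterministic in the seed).
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed; per-stage seeds are derived as
#'   `(seed + 9973 * stage_index) mod (2^31 - 1)`.
#' @param stages subset of simulate, prep, switch, enrich, eisa, atac, motifs.
#' @param n_draws Monte Carlo draws for the enrichment stage.
#' @return list of class `run_manifest` with per-stage outputs, timings,
#'   `config_hash`, `seed` and `version`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         seed = config$seed, stages = pipeline_stages,
                         n_draws = 1e5) {
  stopifnot(all(stages %in% pipeline_stages))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(stages = list(), seed = seed,
                   config_hash = config_hash(config),
                   version = as.character(utils::packageVersion("coneswitch")))
  results <- list()
  need <- function(stage) {
    if (is.null(results[[stage]]))
      stop(sprintf("missing upstream output: rerun stage '%s'", stage))
    results[[stage]]
  }
  timed <- function(name, paths, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    manifest$stages[[name]] <<- list(outputs = paths,
                                     seconds = proc.time()[["elapsed"]] - t0)
    value
  }

  # the simulation is cheap and deterministic, so downstream-only runs
  # regenerate it in memory rather than re-reading every staged file
  if (any(c("simulate", "prep", "switch", "enrich", "eisa", "atac", "motifs") %in% stages)) {
    s_seed <- stage_seed(seed, 1L)
    results$simulate <- list(
      expr = simulate_expression(config, seed = s_seed),
      ei = NULL, peaks = NULL)
    if (any(c("eisa", "simulate") %in% stages))
      results$simulate$ei <- simulate_exon_intron(config, results$simulate$expr,
                                                  seed = stage_seed(seed, 2L))
    if (any(c("atac", "motifs", "simulate") %in% stages))
      results$simulate$peaks <- simulate_peaks(config, seed = stage_seed(seed, 3L))
  }

  if ("simulate" %in% stages) {
    sim <- results$simulate
    paths <- file.path(out_dir, c("counts.tsv", "samples.tsv", "annotation.tsv",
                                  "pathways.tsv", "truth_genes.tsv",
                                  "exonic_counts.tsv", "intronic_counts.tsv",
                                  "peaks.bed", "peak_counts.tsv", "tss.tsv",
                                  "truth_peaks.tsv", "genome.fa", "motifs.pfm"))
    timed("simulate", paths, {
      write_count_matrix(sim$expr$counts, paths[1], paths[2])
      write_gene_annotation(sim$expr$annotation, paths[3], paths[4])
      write_tsv(sim$expr$truth, paths[5])
      write_count_matrix(sim$ei$exonic, paths[6], file.path(out_dir, "samples.tsv"))
      write_count_matrix(sim$ei$intronic, paths[7], file.path(out_dir, "samples.tsv"))
      write_bed(sim$peaks$peaks, paths[8])
      write_tsv(data.frame(name = rownames(sim$peaks$counts), sim$peaks$counts,
                           check.names = FALSE), paths[9])
      write_tsv(sim$peaks$tss, paths[10])
      write_tsv(sim$peaks$truth, paths[11])
      write_fasta(sim$peaks$genome, paths[12])
      write_jaspar_pfm(sim$peaks$motifs, paths[13])
      NULL
    })
  }

  if ("prep" %in% stages) {
    sim <- need("simulate")
    results$prep <- timed("prep", file.path(out_dir, c("log2_expr.tsv", "threshold_scan.tsv")), {
      prep <- prep_expression(sim$expr$counts, seed = stage_seed(seed, 4L))
      write_tsv(data.frame(gene_id = rownames(prep$log2_expr$values),
                           prep$log2_expr$values, check.names = FALSE),
                file.path(out_dir, "log2_expr.tsv"))
      write_tsv(data.frame(threshold = prep$scan$grid,
                           skewness = prep$scan$skewness,
                           n_retained = prep$scan$n_retained),
                file.path(out_dir, "threshold_scan.tsv"))
      prep
    })
  }

  if ("switch" %in% stages) {
    sim <- need("simulate"); prep <- need("prep")
    results$switch <- timed("switch", file.path(out_dir, c("switch_table.tsv", "pca.tsv",
                                                           "sample_correlations.tsv")), {
      lg <- prep$log2_expr
      fc <- fold_changes(lg)
      counts <- sim$expr$counts
      sel <- counts$day != 6
      grp <- factor(counts$day[sel] > 6, labels = c("pre", "post"))
      tst <- nb_lrt_test(counts$counts[rownames(lg$values), sel, drop = FALSE], grp)
      sw <- classify(fc, tst)
      pca <- pca_timecourse(lg)
      corr <- sample_correlations(log2(counts$counts[rownames(lg$values), ] + 1))
      write_tsv(sw, file.path(out_dir, "switch_table.tsv"))
      write_tsv(data.frame(day = rownames(pca$scores), pca$scores,
                           check.names = FALSE), file.path(out_dir, "pca.tsv"))
      write_tsv(data.frame(sample = rownames(corr), corr, check.names = FALSE),
                file.path(out_dir, "sample_correlations.tsv"))
      list(switch_table = sw, pca = pca, correlations = corr, test = tst)
    })
  }

  if ("enrich" %in% stages) {
    sim <- need("simulate"); sw <- need("switch")
    results$enrich <- timed("enrich", file.path(out_dir, c("tf_bins.tsv", "pathways_test.tsv")), {
      fc <- stats::setNames(sw$switch_table$log2_fc, sw$switch_table$gene_id)
      ann <- sim$expr$annotation
      is_tf <- stats::setNames(ann$genes$is_tf, ann$genes$gene_id)[names(fc)]
      e_seed <- stage_seed(seed, 5L)
      bin_sizes <- c(100L, 200L, 300L, 400L, 500L, 600L)
      bin_sizes <- bin_sizes[bin_sizes <= length(fc)]
      bins <- lapply(c(on = "on", off = "off"), function(dir) {
        bs <- tf_bin_frequencies(fc, is_tf, direction = dir, bin_sizes = bin_sizes)
        p <- vapply(seq_along(bs$bin_sizes), function(i)
          permutation_frequency_test(bs$observed_count[i], bs$bin_sizes[i],
                                     is_tf, n_draws = n_draws,
                                     seed = e_seed + i)$p_value, numeric(1))
        data.frame(direction = dir, bin_size = bs$bin_sizes,
                   frequency = bs$frequency, p_value = p,
                   total_frequency = bs$total_frequency)
      })
      sets <- c(ann$pathways,
                list(cone_specific = ann$genes$gene_id[ann$genes$is_cone_specific]))
      pw <- do.call(rbind, lapply(names(sets), function(nm) {
        res <- suppressWarnings(
          pathway_switch_test(fc, sets[[nm]], n_draws = n_draws,
                              seed = e_seed + 100L + match(nm, names(sets))))
        data.frame(pathway = nm, n_genes = length(intersect(sets[[nm]], names(fc))),
                   mean_log2_fc = res$observed_stat, p_value = res$p_value,
                   direction = res$sign, below_resolution = res$below_resolution)
      }))
      write_tsv(do.call(rbind, bins), file.path(out_dir, "tf_bins.tsv"))
      write_tsv(pw, file.path(out_dir, "pathways_test.tsv"))
      list(tf_bins = bins, pathways = pw)
    })
  }

  if ("eisa" %in% stages) {
    sim <- need("simulate")
    results$eisa <- timed("eisa", file.path(out_dir, c("eisa_deltas.tsv", "eisa_summary.tsv")), {
      sd <- split_deltas(sim$ei$exonic, sim$ei$intronic)
      res <- transcriptional_fraction(sd)
      write_tsv(sd$deltas, file.path(out_dir, "eisa_deltas.tsv"))
      write_tsv(data.frame(pearson_r = res$pearson_r,
                           transcriptional_fraction = res$transcriptional_fraction,
                           n_genes = res$n_genes, n_excluded = res$n_excluded),
                file.path(out_dir, "eisa_summary.tsv"))
      list(deltas = sd, result = res)
    })
  }

  if ("atac" %in% stages) {
    sim <- need("simulate")
    results$atac <- timed("atac", file.path(out_dir, c("peak_table.tsv", "ctcf_groups.tsv")), {
      ps <- sim$peaks
      filt <- remove_top_peaks(ps$counts, ps$peaks, k = 10L)
      ch36 <- peak_change(filt$counts, ps$sample_day, 3, 6)
      ch610 <- peak_change(filt$counts, ps$sample_day, 6, 10)
      dist <- nearest_tss_distance(filt$peaks, ps$tss)
      ctcf <- count_ctcf_sites(filt$peaks, ps$genome, ps$motifs[[1L]])
      strat <- ctcf_stratified_change(ch36$log2_fc, ctcf)
      tab <- data.frame(filt$peaks, width_bp = filt$peaks$end - filt$peaks$start,
                        tss_distance = dist, ctcf_sites = ctcf,
                        log2_fc_3_6 = ch36$log2_fc, fdr_3_6 = ch36$fdr,
                        class_3_6 = ch36$change_class,
                        log2_fc_6_10 = ch610$log2_fc, fdr_6_10 = ch610$fdr,
                        class_6_10 = ch610$change_class)
      write_tsv(tab, file.path(out_dir, "peak_table.tsv"))
      write_tsv(strat$summary, file.path(out_dir, "ctcf_groups.tsv"))
      list(table = tab, change_3_6 = ch36, change_6_10 = ch610,
           ctcf_groups = strat, distance = dist, ctcf_sites = ctcf,
           peaks = filt$peaks)
    })
  }

  if ("motifs" %in% stages) {
    sim <- need("simulate"); atac <- need("atac")
    results$motifs <- timed("motifs", file.path(out_dir, "motif_coefficients.tsv"), {
      design <- build_design(atac$peaks, sim$peaks$genome, sim$peaks$motifs,
                             response = atac$change_3_6$log2_fc)
      gs <- grid_search(design, seed = stage_seed(seed, 6L))
      ranking <- rank_contributions(gs)
      write_tsv(cbind(ranking, alpha = gs$alpha, lambda = gs$lambda,
                      cv_mse = gs$cv_mse),
                file.path(out_dir, "motif_coefficients.tsv"))
      list(design = design, search = gs, ranking = ranking)
    })
  }

  manifest$results <- results
  yaml::write_yaml(list(seed = manifest$seed, config_hash = manifest$config_hash,
                        version = manifest$version,
                        stages = lapply(manifest$stages, function(s)
                          list(outputs = as.list(s$outputs),
                               seconds = round(s$seconds, 3)))),
                   file.path(out_dir, "manifest.yaml"))
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("run_manifest: seed %d, config %s\n", x$seed, x$config_hash))
  for (nm in names(x$stages))
    cat(sprintf("  %-9s %6.2f s, %d file(s)\n", nm, x$stages[[nm]]$seconds,
                length(x$stages[[nm]]$outputs)))
  invisible(x)
}
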