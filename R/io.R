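#' Construct a validated count matrix
#'
#' Container for gene-level read counts over a developmental time course:
#' non-negative integer counts (genes x samples) together with the postnatal
#' day and replicate of every sample and the length of every gene.
#'
#' @param counts integer matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids).
#' @param day integer vector, postnatal day per sample.
#' @param replicate integer vector, replicate index per sample.
#' @param gene_length positive integer vector, transcript length in bp per gene.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, day, replicate, gene_length) {
  assert_count_matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop(sprintf("duplicate gene id: '%s'",
                 rownames(counts)[duplicated(rownames(counts))][1L] %||% "<missing rownames>"))
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (length(day) != ncol(counts) || anyNA(day))
    stop(sprintf("sample without metadata: '%s'",
                 colnames(counts)[which(is.na(day))[1L]] %||% "day labels missing"))
  if (length(replicate) != ncol(counts))
    stop("replicate labels must match the number of samples")
  if (length(gene_length) != nrow(counts) || any(!is.finite(gene_length) | gene_length <= 0))
    stop("gene_length must be positive for every gene")
  structure(
    list(counts = counts, day = as.integer(day), replicate = as.integer(replicate),
         gene_length = as.numeric(gene_length)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, days %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(range(x$day), collapse = "-")))
  invisible(x)
}

#' Read a count matrix with its sample metadata
#'
#' The counts file is a TSV with columns `gene_id`, `length`, then one column
#' per sample. The metadata file is a TSV with columns `sample`, `day`,
#' `replicate` mapping every sample id to its day and replicate.
#'
#' @param path path to the counts TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length") %in% names(tab)))
    stop("counts TSV must have 'gene_id' and 'length' columns")
  if (anyDuplicated(tab$gene_id))
    stop(sprintf("duplicate gene id: '%s'", tab$gene_id[duplicated(tab$gene_id)][1L]))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "day", "replicate") %in% names(meta)))
    stop("metadata TSV must have 'sample', 'day', 'replicate' columns")
  sample_cols <- setdiff(names(tab), c("gene_id", "length"))
  missing <- setdiff(sample_cols, meta$sample)
  if (length(missing))
    stop(sprintf("sample without metadata: '%s'", missing[1L]))
  m <- as.matrix(tab[, sample_cols, drop = FALSE])
  rownames(m) <- tab$gene_id
  idx <- match(sample_cols, meta$sample)
  count_matrix(m, day = meta$day[idx], replicate = meta$replicate[idx],
               gene_length = tab$length)
}

#' Write a count matrix and its metadata as TSV
#'
#' Inverse of [read_count_matrix()]; the round trip is lossless.
#'
#' @param x a [count_matrix()].
#' @param path,metadata_path output paths for counts and metadata TSVs.
#' @export
write_count_matrix <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), length = x$gene_length,
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = colnames(x$counts), day = x$day, replicate = x$replicate)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read genomic intervals from a BED3+ file
#'
#' Coordinates are 0-based, half-open (the BED convention used throughout the
#' package): the interval length is `end - start`.
#'
#' @param path path to a tab-separated BED file with at least 3 columns;
#'   columns 4 (name) and 6 (strand) are captured when present.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name` and `strand`, in file order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BED file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("line %d: fewer than 3 BED columns", which(nf < 3L)[1L]))
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("line %d: invalid interval (need 0 <= start < end)", bad[1L]))
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 6L)) out$strand <- vapply(fields, `[[`, "", 6L)
  out
}

#' Write genomic intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `strand` columns (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- c("chrom", "start", "end")
  if (!is.null(intervals$name)) {
    cols <- c(cols, "name")
    if (!is.null(intervals$strand)) {
      intervals$score <- 0L
      cols <- c(cols, "score", "strand")
    }
  }
  utils::write.table(
    format(intervals[, cols], scientific = FALSE, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(intervals)
}

#' Read a genome or peak sequence FASTA
#'
#' Sequences are upper-cased; `N` bases are allowed. Duplicate headers and
#' empty records are errors.
#'
#' @param path FASTA path.
#' @return a named [Biostrings::DNAStringSet] mapping record name to sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop(sprintf("duplicate FASTA header: '%s'",
                 names(seqs)[duplicated(names(seqs))][1L]))
  if (any(Biostrings::width(seqs) == 0L))
    stop(sprintf("empty FASTA record: '%s'",
                 names(seqs)[Biostrings::width(seqs) == 0L][1L]))
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(seqs)
}

#' Construct a position weight matrix model
#'
#' Stores raw base counts, background frequencies and the pseudocount, and
#' derives the log-odds scoring matrix
#' `log2(((count + pseudocount * bg) / (colsum + pseudocount)) / bg)`,
#' i.e. the pseudocount is distributed over bases by the background.
#'
#' @param motif_id identifier.
#' @param counts 4 x L non-negative numeric matrix with rows A, C, G, T.
#' @param background length-4 probabilities (A, C, G, T) summing to 1.
#' @param pseudocount positive real, default 0.8.
#' @return an object of class `pwm_model` with elements `motif_id`, `counts`,
#'   `background`, `pseudocount`, `log_odds` (4 x L) and `max_score`.
#' @export
pwm_model <- function(motif_id, counts, background = rep(0.25, 4), pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L || ncol(counts) < 1L)
    stop("PWM counts must be a 4 x L matrix (rows A, C, G, T)")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop(sprintf("negative or non-finite PWM count in motif '%s'", motif_id))
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0))
    stop("background must be 4 non-negative probabilities summing to 1")
  if (!is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  rownames(counts) <- c("A", "C", "G", "T")
  csum <- colSums(counts)
  lo <- log2(sweep(counts + pseudocount * background, 2, csum + pseudocount, "/") / background)
  if (any(!is.finite(lo))) stop("log-odds matrix not finite; check background/pseudocount")
  structure(list(motif_id = motif_id, counts = counts,
                 background = background, pseudocount = pseudocount,
                 log_odds = lo, max_score = sum(apply(lo, 2, max))),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model '%s': length %d, max log2-odds %.2f\n",
              x$motif_id, ncol(x$counts), x$max_score))
  invisible(x)
}

#' Read motifs from a JASPAR-style PFM text file
#'
#' Accepts blocks of the form `>ID name` followed by four rows of counts in
#' A, C, G, T order; rows may be bare numbers or JASPAR's `A [ 1 2 3 ]` style.
#'
#' @param path PFM text file.
#' @param pseudocount,background passed to [pwm_model()].
#' @return list of [pwm_model()] objects, one per block.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.8, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' motif headers found")
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(header, "\\s+")[[1L]][1L]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L)
      stop(sprintf("motif '%s': expected 4 count rows, found %d", id, length(body)))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop(sprintf("motif '%s': rows of unequal length", id))
    pwm_model(id, do.call(rbind, rows), background = background,
              pseudocount = pseudocount)
  })
}

#' Write motifs to a JASPAR-style PFM text file
#'
#' @param pwms list of [pwm_model()] objects.
#' @param path output path.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$motif_id),
      vapply(1:4, function(r)
        paste0(c("A", "C", "G", "T")[r], " [ ",
               paste(format(p$counts[r, ], trim = TRUE), collapse = " "), " ]"),
        character(1)))
  }))
  writeLines(lines, path)
  invisible(pwms)
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `chromosome`, `tss_bp` (0-based),
#'   `strand` (+/-), `is_tf`, `is_cone_specific` (logical or 0/1).
#' @param pathways_path optional TSV with columns `pathway`, `gene_id`.
#' @return list with `genes` (data.frame) and `pathways` (named list of
#'   gene-id character vectors; empty when no pathway file given).
#' @export
read_gene_annotation <- function(path, pathways_path = NULL) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "tss_bp", "strand", "is_tf", "is_cone_specific")
  if (!all(need %in% names(g)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_id))
    stop(sprintf("duplicate gene id in annotation: '%s'",
                 g$gene_id[duplicated(g$gene_id)][1L]))
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  g$is_tf <- as.logical(g$is_tf)
  g$is_cone_specific <- as.logical(g$is_cone_specific)
  pathways <- list()
  if (!is.null(pathways_path)) {
    pw <- utils::read.delim(pathways_path, stringsAsFactors = FALSE)
    pathways <- split(pw$gene_id, pw$pathway)
  }
  list(genes = g, pathways = pathways)
}

#' Write a gene annotation table (and optional pathway membership)
#'
#' @param annotation list with `genes` and `pathways`, as returned by
#'   [read_gene_annotation()] or [simulate_expression()].
#' @param path,pathways_path output TSV paths.
#' @export
write_gene_annotation <- function(annotation, path, pathways_path = NULL) {
  utils::write.table(annotation$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(pathways_path)) {
    pw <- data.frame(
      pathway = rep(names(annotation$pathways), lengths(annotation$pathways)),
      gene_id = unlist(annotation$pathways, use.names = FALSE))
    utils::write.table(pw, pathways_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(annotation)
}
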