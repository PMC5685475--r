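# Synthetic motif library used by the peak simulator and the motif-regression
# examples. All matrices are constructed here in code; none is copied from a
# motif database. The first motif is a CTCF-like, high-information 19-bp
# zinc-finger-style matrix; the rest are unrelated decoys.

#' Synthetic CTCF-like position weight matrix
#'
#' A 19-bp, GC-rich, high-information synthetic matrix emulating the length
#' and information content of the CTCF zinc-finger footprint. It is not a
#' database matrix; it exists so that planted sites are unambiguous and the
#' scanner can be validated exactly.
#'
#' @param pseudocount,background passed to [pwm_model()].
#' @return a [pwm_model()] with `motif_id = "CTCF_like_synthetic"`.
#' @export
ctcf_like_pwm <- function(pseudocount = 0.8, background = rep(0.25, 4)) {
  consensus <- "CCAGCAGGGGGCGCTGTCA"
  # per-column information: 13 strong columns (85/100) and 6 medium (55/100)
  medium <- c(3L, 6L, 12L, 15L, 17L, 19L)
  build_pfm_from_consensus("CTCF_like_synthetic", consensus,
                           major = ifelse(seq_len(nchar(consensus)) %in% medium, 55L, 85L),
                           depth = 100L,
                           pseudocount = pseudocount, background = background)
}

#' Synthetic motif library (CTCF-like matrix plus decoys)
#'
#' The default motif set scanned by the accessibility analyses: one dominant
#' CTCF-like matrix and eight unrelated synthetic decoy motifs of length
#' 8-12 bp with moderate information content.
#'
#' @param pseudocount,background passed to [pwm_model()].
#' @return named list of [pwm_model()] objects; the first is the CTCF-like one.
#' @export
default_motif_library <- function(pseudocount = 0.8, background = rep(0.25, 4)) {
  decoy_consensus <- c(
    decoy_AT_rich   = "TTAATTAA",
    decoy_ebox      = "CACGTGAC",
    decoy_gata      = "AGATAAGA",
    decoy_fork      = "TGTTTACTTT",
    decoy_zn1       = "GGGTGGGGC",
    decoy_homeo     = "TAATCCGATTA",
    decoy_nuclear   = "AGGTCAAAGGTCA",
    decoy_ets       = "ACCGGAAGTG")
  pwms <- c(list(ctcf_like_pwm(pseudocount, background)),
            lapply(names(decoy_consensus), function(id)
              build_pfm_from_consensus(id, decoy_consensus[[id]], major = 70L,
                                       depth = 100L, pseudocount = pseudocount,
                                       background = background)))
  names(pwms) <- vapply(pwms, `[[`, "", "motif_id")
  pwms
}

# internal: PFM with `major` counts on the consensus base per column and the
# remainder spread evenly over the other three bases.
build_pfm_from_consensus <- function(id, consensus, major, depth = 100L,
                                     pseudocount = 0.8, background = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  major <- rep_len(major, L)
  cons <- match(strsplit(consensus, "")[[1L]], bases)
  counts <- matrix(0, 4, L, dimnames = list(bases, NULL))
  for (j in seq_len(L)) {
    rest <- (depth - major[j]) / 3
    counts[, j] <- rest
    counts[cons[j], j] <- major[j]
  }
  pwm_model(id, counts, background = background, pseudocount = pseudocount)
}

#' Consensus (maximum log-odds) sequence of a PWM
#'
#' @param pwm a [pwm_model()].
#' @return character scalar; ties resolved toward the first base in A,C,G,T order.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$log_odds)[apply(pwm$log_odds, 2, which.max)], collapse = "")
}
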