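# Small fixtures built in code, shared across test files.

# a tiny hand-checkable count matrix: 3 genes x 4 samples (2 days x 2 reps)
tiny_counts <- function() {
  m <- matrix(c(10L, 0L, 5L,
                20L, 1L, 5L,
                40L, 2L, 5L,
                80L, 3L, 5L), nrow = 3,
              dimnames = list(c("gA", "gB", "gC"),
                              c("d0_r1", "d0_r2", "d1_r1", "d1_r2")))
  count_matrix(m, day = c(0L, 0L, 1L, 1L), replicate = c(1L, 2L, 1L, 2L),
               gene_length = c(1000L, 2000L, 500L))
}

# brute-force PWM scorer: per-offset double loop, both strands, used as the
# independent oracle for scan_pwm()
brute_force_pwm_count <- function(pwm, seq, cutoff = 10) {
  eff <- min(cutoff, pwm$max_score) - 1e-9
  count_one <- function(s, W) {
    chars <- strsplit(s, NULL)[[1L]]
    w <- ncol(W)
    n <- 0L
    if (length(chars) < w) return(0L)
    for (i in seq_len(length(chars) - w + 1L)) {
      sc <- 0
      ok <- TRUE
      for (j in seq_len(w)) {
        b <- match(chars[i + j - 1L], c("A", "C", "G", "T"))
        if (is.na(b)) { ok <- FALSE; break }
        sc <- sc + W[b, j]
      }
      if (ok && sc >= eff) n <- n + 1L
    }
    n
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, NULL)[[1L]]), collapse = ""))
  count_one(seq, pwm$log_odds) + count_one(rc, pwm$log_odds)
}

# random DNA of given length
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# small default config for fast tests
test_config <- function(...) {
  simulation_config(n_genes = 600L, n_peaks = 400L, ...)
}
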