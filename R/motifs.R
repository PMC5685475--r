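# Elastic-net model of accessibility change: per-peak motif hit counts plus
# composition covariates (peak width, G+C count, CpG count) predict the log2
# fold change of accessibility. glmnet does the heavy lifting; a
# coordinate-descent refinement drives every reported solution to a strict
# KKT tolerance, and lambda = 0 is solved as exact ordinary least squares.

#' Build the motif design matrix for accessibility regression
#'
#' One column per motif (PWM hit counts from [scan_pwm()] at the effective
#' cutoff) plus three composition covariates: `width_bp`, `gc_count`
#' (number of G + C bases) and `cpg_count` (occurrences of the dinucleotide
#' CG; overlapping occurrences would each count, though none exist for a
#' 2-mer). Peaks whose sequence is more than 50% N are excluded and reported.
#'
#' @param peaks BED-style data.frame.
#' @param genome named `DNAStringSet`.
#' @param pwms list of [pwm_model()] objects.
#' @param response optional per-peak response (e.g. accessibility log2 fold
#'   change) to carry along, filtered consistently.
#' @param cutoff nominal log2-odds cutoff for the scanner.
#' @return list of class `design_matrix` with `x` (peaks x predictors),
#'   `y` (response or NULL), `covariates` (covariate column names),
#'   `excluded` (names of dropped peaks).
#' @export
build_design <- function(peaks, genome, pwms, response = NULL, cutoff = 10) {
  stopifnot(length(pwms) >= 1L)
  seqs <- peak_sequences(peaks, genome)
  nm <- peaks$name %||% (rownames(peaks) %||% as.character(seq_len(nrow(peaks))))
  n_count <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs), "N")[, 1L]
  keep <- n_count <= 0.5 * nchar(seqs)
  motif_cols <- do.call(cbind, lapply(pwms, function(p)
    scan_pwm(p, seqs, cutoff = cutoff)))
  colnames(motif_cols) <- vapply(pwms, `[[`, "", "motif_id")
  ss <- Biostrings::DNAStringSet(seqs)
  x <- cbind(motif_cols,
             width_bp = peaks$end - peaks$start,
             gc_count = Biostrings::letterFrequency(ss, "GC")[, 1L],
             cpg_count = Biostrings::vcountPattern("CG", ss))
  rownames(x) <- nm
  if (anyDuplicated(colnames(x))) stop("duplicate predictor names")
  structure(list(x = x[keep, , drop = FALSE],
                 y = if (!is.null(response)) response[keep] else NULL,
                 covariates = c("width_bp", "gc_count", "cpg_count"),
                 excluded = nm[!keep]),
            class = "design_matrix")
}

# internal: standardize columns to mean 0, variance 1 (1/n denominator);
# zero-variance columns are reported, not scaled
standardize_columns <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sd_n <- sqrt(colMeans(sweep(x, 2, mu)^2))
  keep <- sd_n > 0
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd_n[keep], "/")
  list(xs = xs, mu = mu, sd = sd_n, keep = keep)
}

# internal: max KKT residual of the elastic-net objective
# (1/2n)||y - b0 - X b||^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
# on standardized predictors
kkt_residual <- function(xs, yc, b, alpha, lambda) {
  n <- nrow(xs)
  r <- yc - as.numeric(xs %*% b)
  g <- -as.numeric(crossprod(xs, r)) / n + lambda * (1 - alpha) * b
  res <- ifelse(b != 0,
                abs(g + lambda * alpha * sign(b)),
                pmax(0, abs(g) - lambda * alpha))
  max(res)
}

# internal: cyclic coordinate descent to a strict KKT tolerance, warm start b
cd_refine <- function(xs, yc, b, alpha, lambda, tol = 1e-9, max_sweeps = 5000L) {
  n <- nrow(xs)
  p <- ncol(xs)
  r <- yc - as.numeric(xs %*% b)
  denom <- 1 + lambda * (1 - alpha)   # columns have variance 1 (1/n)
  thr <- lambda * alpha
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      z <- sum(xs[, j] * r) / n + b[j]
      bj <- sign(z) * max(0, abs(z) - thr) / denom
      if (bj != b[j]) {
        r <- r - (bj - b[j]) * xs[, j]
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (delta < tol / 10 && kkt_residual(xs, yc, b, alpha, lambda) < tol) break
  }
  b
}

#' Fit an elastic net at a fixed alpha and lambda
#'
#' Objective: `(1/2n) RSS + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)`
#' on standardized predictors (zero mean, unit 1/n variance; zero-variance
#' columns are dropped with a warning), coefficients reported back on the
#' original predictor scale. `lambda = 0` is solved as exact OLS. The
#' returned solution satisfies the KKT optimality conditions to within 1e-9
#' on the standardized scale.
#'
#' @param x predictors (matrix or `design_matrix`).
#' @param y response (taken from the design when omitted).
#' @param alpha L1/L2 mixing in `[0, 1]`.
#' @param lambda penalty strength `>= 0`.
#' @return list of class `elastic_net_fit` with `beta` (original scale,
#'   named), `intercept`, `alpha`, `lambda`, `beta_std`, `kkt`,
#'   `covariates`.
#' @export
elastic_net_fit <- function(x, y = NULL, alpha, lambda) {
  covariates <- character(0)
  if (inherits(x, "design_matrix")) {
    if (is.null(y)) y <- x$y
    covariates <- x$covariates
    x <- x$x
  }
  stopifnot(is.matrix(x), length(y) == nrow(x), alpha >= 0, alpha <= 1,
            lambda >= 0)
  if (nrow(x) < 2L) stop("need at least 2 observations")
  st <- standardize_columns(x)
  if (any(!st$keep))
    warning(sprintf("dropping zero-variance predictor(s): %s",
                    paste(colnames(x)[!st$keep], collapse = ", ")))
  xs <- st$xs
  n <- nrow(xs)
  ybar <- mean(y)
  yc <- y - ybar

  if (lambda == 0) {
    b <- stats::lm.fit(xs, yc)$coefficients
    b[is.na(b)] <- 0
  } else {
    lam_seq <- sort(unique(c(lambda * 10^seq(2, 0, length.out = 20))),
                    decreasing = TRUE)
    fit <- glmnet::glmnet(xs, yc, alpha = alpha, lambda = lam_seq,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-12, maxit = 1e6)
    b <- as.numeric(stats::coef(fit, s = lambda)[-1L])
    b <- cd_refine(xs, yc, b, alpha, lambda)
  }
  names(b) <- colnames(xs)
  kkt <- if (lambda > 0) kkt_residual(xs, yc, b, alpha, lambda) else
    max(abs(crossprod(xs, yc - as.numeric(xs %*% b)) / n))

  beta <- stats::setNames(rep(0, ncol(x)), colnames(x))
  beta[st$keep] <- b / st$sd[st$keep]
  intercept <- ybar - sum(beta[st$keep] * st$mu[st$keep])
  structure(list(beta = beta, intercept = intercept, alpha = alpha,
                 lambda = lambda, beta_std = b, kkt = kkt,
                 covariates = covariates),
            class = "elastic_net_fit")
}

#' @export
print.elastic_net_fit <- function(x, ...) {
  cat(sprintf("elastic_net_fit: alpha %.2f, lambda %.4g, %d of %d nonzero, KKT %.2g\n",
              x$alpha, x$lambda, sum(x$beta != 0), length(x$beta), x$kkt))
  invisible(x)
}

#' Alpha/lambda grid search with cross-validated MSE
#'
#' For every alpha on the grid (0 to 1 in steps of 0.1 by default) a
#' 100-point lambda path spanning four decades below that alpha's
#' lambda-max is evaluated by 5-fold cross-validation (identical folds
#' across grid points, assigned by a seeded shuffle); the winner is the
#' (alpha, lambda) pair with the overall minimal CV mean squared error,
#' ties going to the larger lambda (sparser model). The winning model is
#' refitted with [elastic_net_fit()].
#'
#' @param x predictors (matrix or `design_matrix`).
#' @param y response (taken from the design when omitted).
#' @param alphas alpha grid.
#' @param n_folds CV folds (default 5).
#' @param lambda_path_length points per lambda path (default 100).
#' @param seed integer seed for fold assignment.
#' @return list of class `grid_search` with `alpha`, `lambda`, `cv_mse`,
#'   `fit` (the refit [elastic_net_fit()]) and `cv_table` (per grid point).
#' @export
grid_search <- function(x, y = NULL, alphas = seq(0, 1, by = 0.1),
                        n_folds = 5L, lambda_path_length = 100L, seed = 1L) {
  design <- NULL
  if (inherits(x, "design_matrix")) {
    design <- x
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  stopifnot(nrow(x) >= n_folds)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(n_folds), nrow(x)))
  st <- standardize_columns(x)
  xs <- st$xs
  rows <- list()
  for (a in alphas) {
    cv <- glmnet::cv.glmnet(xs, y, alpha = a, foldid = foldid,
                            nlambda = lambda_path_length,
                            lambda.min.ratio = 1e-4,
                            standardize = FALSE, thresh = 1e-10)
    rows[[length(rows) + 1L]] <-
      data.frame(alpha = a, lambda = cv$lambda, cv_mse = cv$cvm)
  }
  tab <- do.call(rbind, rows)
  best_mse <- min(tab$cv_mse)
  cand <- tab[tab$cv_mse == best_mse, , drop = FALSE]
  cand <- cand[order(-cand$lambda), , drop = FALSE]   # ties -> sparser
  alpha <- cand$alpha[1L]
  lambda <- cand$lambda[1L]
  fit <- elastic_net_fit(design %||% x, y, alpha = alpha, lambda = lambda)
  structure(list(alpha = alpha, lambda = lambda, cv_mse = best_mse,
                 fit = fit, cv_table = tab, foldid = foldid),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("grid_search: best alpha %.1f, lambda %.4g (CV MSE %.4g)\n",
              x$alpha, x$lambda, x$cv_mse))
  invisible(x)
}

#' Rank predictors by absolute coefficient
#'
#' Predictors with nonzero coefficients, sorted by |beta| descending;
#' composition covariates are flagged so motif contributions can be read
#' separately.
#'
#' @param fit an [elastic_net_fit()] (or a `grid_search`, whose final fit is
#'   used).
#' @param covariates covariate names to flag; defaults to those recorded in
#'   the fit.
#' @return data.frame: `predictor`, `beta`, `abs_beta`, `is_covariate`,
#'   sorted by `abs_beta` descending; zero-beta predictors omitted.
#' @export
rank_contributions <- function(fit, covariates = NULL) {
  if (inherits(fit, "grid_search")) fit <- fit$fit
  stopifnot(inherits(fit, "elastic_net_fit"))
  covariates <- covariates %||% fit$covariates
  b <- fit$beta[fit$beta != 0]
  out <- data.frame(predictor = names(b), beta = as.numeric(b),
                    abs_beta = abs(as.numeric(b)),
                    is_covariate = names(b) %in% covariates,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_beta, out$predictor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
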