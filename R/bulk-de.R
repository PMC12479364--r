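## Differential-expression engine: filtering, TMM normalization,
## precision-weighted linear modelling, empirical-Bayes moderation,
## fold-change-thresholded (TREAT-style) testing, BH adjustment and
## directional calls. Every signature rule downstream consumes the
## {-1, 0, +1} calls this module produces.

#' Sum technical replicates into biological samples
#'
#' Columns belonging to the same replicate group (e.g. two sequencing runs
#' of one library) are summed; the group label becomes the sample id.
#'
#' @param counts genes x samples integer matrix.
#' @param replicate_groups character vector, one group label per column.
#' @return genes x groups integer matrix.
#' @export
sum_technical_replicates <- function(counts, replicate_groups) {
  check_count_matrix(counts)
  if (length(replicate_groups) != ncol(counts)) {
    stopf("replicate_groups has length %d but counts has %d columns",
          length(replicate_groups), ncol(counts))
  }
  if (anyNA(replicate_groups)) stopf("every sample must be assigned to a replicate group")
  groups <- unique(as.character(replicate_groups))
  out <- vapply(groups, function(g) {
    rowSums(counts[, replicate_groups == g, drop = FALSE])
  }, numeric(nrow(counts)))
  dimnames(out) <- list(rownames(counts), groups)
  storage.mode(out) <- "integer"
  attr(out, "orientation") <- attr(counts, "orientation")
  out
}

#' Drop samples with small library sizes
#'
#' Samples whose total count is strictly below `min_reads` are removed
#' (default 1 million reads, the conventional floor for bulk libraries).
#'
#' @param counts genes x samples matrix.
#' @param min_reads library-size floor; strictly-below samples are dropped.
#' @return filtered matrix with a `dropped_samples` attribute.
#' @export
filter_samples_by_library_size <- function(counts, min_reads = 1e6) {
  totals <- colSums(counts)
  drop <- totals < min_reads
  if (all(drop)) stopf("all samples have library size below %g", min_reads)
  if (any(drop)) {
    message(sprintf("dropping %d sample(s) with library size < %g: %s",
                    sum(drop), min_reads,
                    paste(colnames(counts)[drop], collapse = ", ")))
  }
  out <- counts[, !drop, drop = FALSE]
  attr(out, "dropped_samples") <- colnames(counts)[drop]
  out
}

#' Remove lowly expressed genes
#'
#' A gene is kept iff its CPM reaches `min_count` re-expressed on the median
#' library (i.e. CPM >= min_count / median(library)/1e6) in at least as many
#' samples as the smallest experimental group contains, and its total count
#' across all samples is at least `min_total`.
#'
#' @param counts genes x samples matrix.
#' @param group_labels experimental group per sample (defines the smallest
#'   group size `k`).
#' @param min_count per-sample count floor, interpreted on the CPM scale
#'   relative to the median library size.
#' @param min_total floor on the total count over all samples.
#' @return filtered matrix with a `removed_genes` attribute.
#' @export
filter_low_expression <- function(counts, group_labels, min_count = 10,
                                  min_total = 15) {
  if (length(group_labels) != ncol(counts)) {
    stopf("group_labels has length %d but counts has %d columns",
          length(group_labels), ncol(counts))
  }
  tab <- table(as.character(group_labels))
  if (any(tab == 0)) stopf("empty experimental group(s)")
  k <- min(tab)
  lib <- colSums(counts)
  med_lib_millions <- stats::median(lib) / 1e6
  cpm_cutoff <- min_count / med_lib_millions
  cpm <- t(t(counts) / lib * 1e6)
  keep <- rowSums(cpm >= cpm_cutoff) >= k & rowSums(counts) >= min_total
  removed <- rownames(counts)[!keep]
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed_genes") <- removed
  out
}

## M/A statistics and the doubly trimmed, precision-weighted mean underlying
## one TMM factor. Trimming keeps genes whose M-rank and A-rank both fall in
## the central (1 - 2*trim) band.
.tmm_one <- function(obs, ref, lib_obs, lib_ref, trim_M, trim_A) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) stopf("sample shares no positive genes with the TMM reference")
  obs <- obs[pos]; ref <- ref[pos]
  M <- log2((obs / lib_obs) / (ref / lib_ref))
  A <- 0.5 * log2((obs / lib_obs) * (ref / lib_ref))
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; obs <- obs[fin]; ref <- ref[fin]
  n <- length(M)
  if (n == 0L) stopf("sample shares no positive genes with the TMM reference")
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * trim_M) + 1L; hiM <- n + 1L - loM
  loA <- floor(n * trim_A) + 1L; hiA <- n + 1L - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) keep <- rep(TRUE, n)
  ## delta-method precision of M for Poisson-like counts
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  f <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  if (!is.finite(f) || f <= 0) f <- 1
  f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference column
#' (the sample whose 75th-percentile CPM is closest to the mean of those
#' percentiles), log ratios M and average abundances A are computed over
#' genes positive in both; genes in the extreme `trim_M` / `trim_A`
#' quantile tails of M and A are discarded; the factor is 2 to the
#' precision-weighted mean of the surviving M-values. Factors are rescaled
#' to geometric mean 1.
#'
#' @param counts genes x samples matrix (>= 2 samples).
#' @param trim_M,trim_A two-sided trim fractions for the log-ratio and
#'   abundance dimensions.
#' @return numeric vector of per-sample factors, geometric mean 1, with a
#'   `reference` attribute naming the reference sample.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  if (ncol(counts) < 2L) stopf("TMM needs at least two samples")
  if (any(counts < 0)) stopf("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib <= 0)) stopf("zero-total sample(s): %s",
                           paste(colnames(counts)[lib <= 0], collapse = ", "))
  q75 <- apply(counts, 2L, function(y) stats::quantile(y / sum(y), 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref) return(1)
    .tmm_one(counts[, i], counts[, ref], lib[i], lib[ref], trim_M, trim_A)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "reference") <- colnames(counts)[ref] %||% ref
  f
}

#' Log2 counts per million
#'
#' `log2((y + prior) / (L + 2 * prior) * 1e6)` with effective library sizes
#' `L = column sum * normalization factor`.
#'
#' @param counts genes x samples matrix.
#' @param norm_factors per-sample factors (default all 1).
#' @param prior prior count stabilizing zeros.
#' @return genes x samples matrix of log2 CPM values.
#' @export
log_cpm <- function(counts, norm_factors = NULL, prior = 0.5) {
  norm_factors <- norm_factors %||% rep(1, ncol(counts))
  L <- colSums(counts) * norm_factors
  if (any(L <= 0)) stopf("non-positive effective library size")
  out <- log2(t((t(counts) + prior) / (L + 2 * prior)) * 1e6)
  dimnames(out) <- dimnames(counts)
  out
}

#' Mean-variance precision weights
#'
#' Fits each gene by ordinary least squares, smooths the quarter-root
#' residual variances (sqrt of residual sd) against mean log-CPM with
#' `lowess`, predicts a standard deviation at every fitted value, and
#' returns inverse fourth-power weights, so observations on the flat,
#' high-expression part of the mean-variance trend carry more weight.
#'
#' @param logcpm genes x samples matrix of log2 CPM.
#' @param design samples x coefficients design matrix, full column rank.
#' @param span lowess span for the trend.
#' @return genes x samples matrix of strictly positive weights.
#' @export
mean_variance_weights <- function(logcpm, design, span = 0.5) {
  n <- ncol(logcpm); p <- qr(design)$rank
  if (p < ncol(design)) stopf("design matrix is not full column rank")
  if (n <= ncol(design)) stopf("fewer samples (%d) than needed for %d coefficients", n, ncol(design))
  fit <- stats::lm.fit(design, t(logcpm))
  res <- fit$residuals                      # samples x genes
  df <- n - ncol(design)
  sigma <- sqrt(colSums(res^2) / df)
  sx <- rowMeans(logcpm)
  sy <- sqrt(sigma)
  lo <- stats::lowess(sx, sy, f = span)
  fitted_vals <- t(design %*% fit$coefficients)   # genes x samples
  pred_sqrt_sd <- matrix(
    stats::approx(lo$x, lo$y, xout = fitted_vals, rule = 2, ties = mean)$y,
    nrow = nrow(logcpm))
  pred_sqrt_sd <- pmax(pred_sqrt_sd, 1e-4)
  w <- pred_sqrt_sd^(-4)
  dimnames(w) <- dimnames(logcpm)
  w
}

## Newton solve of trigamma(x) = y, vectorized, for the moment estimator of
## the prior degrees of freedom.
.trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (max(-dif / x, na.rm = TRUE) < 1e-10) break
  }
  x
}

## Method-of-moments fit of the scaled-F model for residual variances on the
## log scale: returns prior df d0 and prior variance s0^2.
.fit_fdist <- function(s2, df, d0_cap = 1e6) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(d0 = d0_cap, s02 = exp(emean))
  } else {
    d0 <- min(2 * .trigamma_inverse(evar), d0_cap)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    list(d0 = d0, s02 = s02)
  }
}

#' Weighted linear fits with empirical-Bayes variance moderation
#'
#' Per-gene weighted least squares against a shared design, followed by
#' shrinkage of the residual variances toward a common prior: the prior
#' degrees of freedom `d0` and prior variance `s0^2` are estimated by
#' method-of-moments on the log residual variances, and each gene's
#' posterior variance is the degree-of-freedom-weighted convex combination
#' `(d0 * s0^2 + d * s^2) / (d0 + d)`.
#'
#' @param logcpm genes x samples expression matrix.
#' @param weights genes x samples positive precision weights (all 1 if NULL).
#' @param design samples x coefficients matrix, full column rank.
#' @param contrasts coefficients x contrasts numeric matrix (identity if
#'   NULL); column names label the contrasts.
#' @param d0 force the prior degrees of freedom instead of estimating them
#'   (0 disables moderation; `Inf` is capped at `d0_cap`).
#' @param d0_cap ceiling representing an infinite prior.
#' @return an object of class `gene_fits` holding coefficients, per-contrast
#'   effects and unscaled standard errors, residual and posterior variances,
#'   and the estimated hyperparameters.
#' @export
fit_and_moderate <- function(logcpm, weights = NULL, design,
                             contrasts = NULL, d0 = NULL, d0_cap = 1e6) {
  G <- nrow(logcpm); n <- ncol(logcpm); p <- ncol(design)
  if (nrow(design) != n) stopf("design has %d rows but logcpm has %d samples", nrow(design), n)
  if (qr(design)$rank < p) stopf("design matrix is not full column rank")
  if (n <= p) stopf("zero residual degrees of freedom (n = %d, p = %d)", n, p)
  if (is.null(weights)) weights <- matrix(1, G, n, dimnames = dimnames(logcpm))
  if (any(weights <= 0)) stopf("weights must be strictly positive")
  if (is.null(contrasts)) {
    contrasts <- diag(p)
    dimnames(contrasts) <- list(colnames(design), colnames(design))
  }
  contrasts <- as.matrix(contrasts)
  if (nrow(contrasts) != p) {
    stopf("contrast matrix has %d rows but design has %d coefficients",
          nrow(contrasts), p)
  }
  k <- ncol(contrasts)
  beta <- matrix(NA_real_, G, p, dimnames = list(rownames(logcpm), colnames(design)))
  eff <- matrix(NA_real_, G, k, dimnames = list(rownames(logcpm), colnames(contrasts)))
  u <- matrix(NA_real_, G, k, dimnames = dimnames(eff))
  sigma2 <- numeric(G)
  for (g in seq_len(G)) {
    w <- weights[g, ]
    y <- logcpm[g, ]
    Xw <- design * w
    XtWX <- crossprod(design, Xw)
    V <- chol2inv(chol(XtWX))
    b <- V %*% crossprod(Xw, y)
    r <- y - as.vector(design %*% b)
    sigma2[g] <- sum(w * r^2) / (n - p)
    beta[g, ] <- b
    eff[g, ] <- crossprod(contrasts, b)
    u[g, ] <- sqrt(pmax(colSums(contrasts * (V %*% contrasts)), 0))
  }
  df_resid <- n - p
  if (is.null(d0)) {
    hyper <- .fit_fdist(sigma2, df_resid, d0_cap)
  } else {
    d0 <- min(d0, d0_cap)
    s02 <- if (d0 > 0) .fit_fdist(sigma2, df_resid, d0_cap)$s02 else NA_real_
    hyper <- list(d0 = d0, s02 = s02)
  }
  s2_post <- if (hyper$d0 == 0) {
    sigma2
  } else {
    (hyper$d0 * hyper$s02 + df_resid * sigma2) / (hyper$d0 + df_resid)
  }
  structure(list(
    coefficients = beta, contrasts = contrasts, effects = eff,
    stdev_unscaled = u, sigma2 = sigma2, df_residual = df_resid,
    d0 = hyper$d0, s02 = hyper$s02, s2_post = s2_post,
    amean = rowMeans(logcpm), design = design
  ), class = "gene_fits")
}

#' @export
print.gene_fits <- function(x, ...) {
  cat(sprintf("gene_fits: %d genes, %d coefficients, %d contrast(s)\n",
              nrow(x$coefficients), ncol(x$coefficients), ncol(x$effects)))
  cat(sprintf("  residual df %d, prior df %.4g, prior variance %.4g\n",
              x$df_residual, x$d0, x$s02))
  invisible(x)
}

#' Fold-change-threshold (TREAT-style) test for one contrast
#'
#' Tests H0: |true log2 fold change| <= tau, tau = log2(fc_threshold),
#' with the moderated standard error and d0 + d degrees of freedom; the
#' p-value combines the two one-sided tail tests at +tau and -tau. With
#' `fc_threshold = 1` this reduces exactly to the two-sided moderated t.
#'
#' @param fits a `gene_fits` object.
#' @param contrast contrast name or index among `colnames(fits$effects)`.
#' @param fc_threshold minimal fold change under the null (>= 1).
#' @return a `de_result` data.frame with columns `gene`, `logFC`, `AveExpr`,
#'   `t`, `P.Value`, `adj.P.Val`, plus `tau` and `df_total` attributes.
#' @export
treat_test <- function(fits, contrast = 1L, fc_threshold = 1.1) {
  stopifnot(inherits(fits, "gene_fits"))
  if (fc_threshold < 1) stopf("fc_threshold must be >= 1 (got %g)", fc_threshold)
  if (is.character(contrast) && !contrast %in% colnames(fits$effects)) {
    stopf("unknown contrast '%s'", contrast)
  }
  tau <- log2(fc_threshold)
  lfc <- fits$effects[, contrast]
  se <- fits$stdev_unscaled[, contrast] * sqrt(fits$s2_post)
  df_total <- fits$df_residual + min(fits$d0, 1e6)
  t_right <- (abs(lfc) - tau) / se
  t_left <- (abs(lfc) + tau) / se
  p <- stats::pt(t_right, df = df_total, lower.tail = FALSE) +
    stats::pt(t_left, df = df_total, lower.tail = FALSE)
  p <- pmin(p, 1)
  out <- data.frame(
    gene = rownames(fits$effects),
    logFC = as.numeric(lfc),
    AveExpr = as.numeric(fits$amean),
    t = sign(lfc) * t_right,
    P.Value = as.numeric(p),
    adj.P.Val = adjust_bh(as.numeric(p)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$gene
  attr(out, "tau") <- tau
  attr(out, "df_total") <- df_total
  attr(out, "contrast") <- if (is.character(contrast)) contrast else colnames(fits$effects)[contrast]
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement.
#'
#' @param p_values numeric vector in [0, 1].
#' @return q-values in [0, 1], same order as the input.
#' @export
adjust_bh <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Directional significance calls
#'
#' @param results a `de_result` (or any data.frame with `logFC` and
#'   `adj.P.Val` columns).
#' @param fdr FDR level; the boundary is inclusive (`q <= fdr` is called).
#' @return named integer vector in \{-1, 0, +1\} per gene.
#' @export
decide_directions <- function(results, fdr = 0.05) {
  d <- ifelse(results$adj.P.Val <= fdr, sign(results$logFC), 0)
  stats::setNames(as.integer(d), results$gene)
}

#' Sample-level QC embeddings
#'
#' PCA on gene-centred log-CPM (with per-component variance fractions),
#' classical multidimensional scaling of pairwise "leading" distances (the
#' root-mean-square of the `top_genes` largest per-pair absolute log fold
#' changes), and the relative log expression matrix (log-CPM minus the
#' per-gene median).
#'
#' @param logcpm genes x samples matrix.
#' @param top_genes genes per pair used for the leading distance.
#' @param n_components embedding dimensions to return.
#' @return list with `pca_coords`, `variance_fraction`, `mds_coords`,
#'   `rle_matrix`.
#' @export
qc_embeddings <- function(logcpm, top_genes = 500, n_components = 2) {
  n <- ncol(logcpm)
  if (n < 3L) stopf("QC embeddings need at least 3 samples")
  if (n_components >= n) stopf("cannot extract %d components from %d samples", n_components, n)
  centred <- logcpm - rowMeans(logcpm)
  pc <- stats::prcomp(t(centred), center = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  top_genes <- min(top_genes, nrow(logcpm))
  D <- matrix(0, n, n, dimnames = list(colnames(logcpm), colnames(logcpm)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d2 <- sort((logcpm[, i] - logcpm[, j])^2, decreasing = TRUE)[seq_len(top_genes)]
      D[i, j] <- D[j, i] <- sqrt(mean(d2))
    }
  }
  mds <- stats::cmdscale(D, k = n_components)
  list(
    pca_coords = pc$x[, seq_len(n_components), drop = FALSE],
    variance_fraction = varfrac,
    mds_coords = mds,
    rle_matrix = logcpm - apply(logcpm, 1L, stats::median)
  )
}
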