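## Bounded rank-based single-sample signature scoring: the projection
## primitive. Each sample's genes are ranked (ascending, average ties); a
## signature's score is the mean rank of its genes, min-max normalized by
## the analytic extremes and centred, so up-only scores live in
## [-0.5, +0.5] and bidirectional totals in [-1, +1]. Scores depend only on
## within-sample gene ordering, so any strictly monotone transform of the
## expression values leaves them unchanged.

#' Rank genes within one sample
#'
#' Ascending ranks with average ties; the ranks of N genes always sum to
#' N(N+1)/2.
#'
#' @param expression_vector named numeric vector of finite values.
#' @return named numeric vector of ranks.
#' @export
rank_genes <- function(expression_vector) {
  if (length(expression_vector) == 0L) stopf("cannot rank an empty vector")
  if (anyNA(expression_vector) || any(!is.finite(expression_vector))) {
    stopf("expression values must be finite")
  }
  rank(expression_vector, ties.method = "average")
}

## Normalized, centred mean rank of a gene set: (mean rank - min attainable)
## / (max attainable - min attainable) - 0.5, where for n set genes among N
## the attainable mean-rank extremes are (n+1)/2 and (2N - n + 1)/2.
.centred_mean_rank <- function(ranks, idx) {
  N <- length(ranks); n <- length(idx)
  if (n == 0L) return(NA_real_)
  if (n == N) return(0)   # whole universe: mean rank is fixed at its midpoint
  lo <- (n + 1) / 2
  hi <- (2 * N - n + 1) / 2
  (mean(ranks[idx]) - lo) / (hi - lo) - 0.5
}

#' Rank-based signature score for one sample
#'
#' Signature genes absent from the expression vector are dropped with a
#' warning and the analytic bounds are recomputed on the present subset
#' (projection panels, e.g. targeted spatial assays, rarely carry every
#' signature gene). With a down set, ranks are reversed for the down score
#' and `total = up + down`.
#'
#' @param expression_vector named numeric vector (one sample).
#' @param up_set,down_set character vectors of gene ids; `down_set` may be
#'   NULL for up-only scoring.
#' @param warn_missing emit a warning when signature genes are absent.
#' @return list with `up_score`, `down_score` (NA when no down set),
#'   `total_score`, `n_up_used`, `n_down_used`.
#' @export
signature_score <- function(expression_vector, up_set, down_set = NULL,
                            warn_missing = TRUE) {
  if (is.null(names(expression_vector))) stopf("expression vector must be named")
  ranks <- rank_genes(expression_vector)
  genes <- names(expression_vector)
  up_present <- intersect(up_set, genes)
  if (length(up_present) == 0L) {
    stopf("no up-set gene present in the expression data (%d requested)",
          length(up_set))
  }
  n_missing <- length(up_set) - length(up_present)
  if (n_missing > 0 && warn_missing) {
    warnf("%d of %d up-set gene(s) absent; bounds recomputed on %d present",
          n_missing, length(up_set), length(up_present))
  }
  up_score <- .centred_mean_rank(ranks, match(up_present, genes))
  down_score <- NA_real_
  n_down_used <- 0L
  if (!is.null(down_set) && length(down_set)) {
    down_present <- intersect(down_set, genes)
    if (length(down_present) == 0L) {
      stopf("no down-set gene present in the expression data (%d requested)",
            length(down_set))
    }
    if (length(down_set) > length(down_present) && warn_missing) {
      warnf("%d of %d down-set gene(s) absent; bounds recomputed",
            length(down_set) - length(down_present), length(down_set))
    }
    rev_ranks <- length(ranks) + 1 - ranks
    down_score <- .centred_mean_rank(rev_ranks, match(down_present, genes))
    n_down_used <- length(down_present)
  }
  total <- if (is.na(down_score)) up_score else up_score + down_score
  list(up_score = up_score, down_score = down_score, total_score = total,
       n_up_used = length(up_present), n_down_used = n_down_used)
}

## Coerce the accepted signature containers (gene_signature list,
## gene_set_collection, plain character lists) into a uniform
## list(name -> list(up, down)).
.as_signature_list <- function(signatures) {
  if (inherits(signatures, "gene_signature")) {
    signatures <- stats::setNames(list(signatures), signatures$name)
  }
  if (is.null(names(signatures))) stopf("signatures must be named")
  lapply(signatures, function(s) {
    if (inherits(s, "gene_signature")) list(up = s$up, down = s$down)
    else if (is.character(s)) list(up = s, down = character())
    else if (is.list(s) && !is.null(s$up)) list(up = s$up, down = s$down %||% character())
    else stopf("unsupported signature representation")
  })
}

#' Score every sample against every signature
#'
#' @param expression_matrix genes x samples matrix (any monotone expression
#'   scale: counts, CPM, log-CPM all give identical scores).
#' @param signatures named list of `gene_signature` objects, character
#'   vectors (up-only) or a `gene_set_collection`.
#' @param use `"up_only"` (the projection default) scores only up sets;
#'   `"bidirectional"` adds reversed-rank down scores where a down set
#'   exists.
#' @return samples x signatures numeric score matrix with a `genes_used`
#'   attribute (per signature, genes present in the data).
#' @export
score_matrix <- function(expression_matrix, signatures,
                         use = c("up_only", "bidirectional")) {
  use <- match.arg(use)
  sigs <- .as_signature_list(signatures)
  if (is.null(rownames(expression_matrix))) stopf("expression matrix must have gene row names")
  genes <- rownames(expression_matrix)
  out <- matrix(NA_real_, ncol(expression_matrix), length(sigs),
                dimnames = list(colnames(expression_matrix), names(sigs)))
  used <- list()
  ## precompute rank matrix once: ranks are per-column
  R <- apply(expression_matrix, 2L, rank, ties.method = "average")
  N <- nrow(expression_matrix)
  for (nm in names(sigs)) {
    up <- intersect(sigs[[nm]]$up, genes)
    if (length(up) == 0L) stopf("signature '%s': no up-set gene present", nm)
    if (length(up) < length(sigs[[nm]]$up)) {
      warnf("signature '%s': %d of %d up gene(s) absent from the data",
            nm, length(sigs[[nm]]$up) - length(up), length(sigs[[nm]]$up))
    }
    iu <- match(up, genes)
    sc <- apply(R, 2L, function(r) .centred_mean_rank(r, iu))
    down <- intersect(sigs[[nm]]$down, genes)
    if (use == "bidirectional" && length(down)) {
      id <- match(down, genes)
      sc <- sc + apply(N + 1 - R, 2L, function(r) .centred_mean_rank(r, id))
    }
    out[, nm] <- sc
    used[[nm]] <- list(up = up, down = if (use == "bidirectional") down else character())
  }
  attr(out, "genes_used") <- used
  attr(out, "use") <- use
  out
}

#' Per-cluster mean scores
#'
#' @param scores samples x signatures score matrix.
#' @param labels cluster label per sample.
#' @param zscore additionally z-scale each signature column across clusters
#'   (sample-sd convention).
#' @return clusters x signatures matrix of means (plus `zscores` attribute
#'   when requested).
#' @export
summarize_by_cluster <- function(scores, labels, zscore = FALSE) {
  if (length(labels) != nrow(scores)) {
    stopf("labels length %d does not match %d scored samples", length(labels), nrow(scores))
  }
  labels <- as.character(labels)
  keep <- !is.na(labels)
  if (!all(keep)) warnf("%d sample(s) without a label excluded", sum(!keep))
  scores <- scores[keep, , drop = FALSE]; labels <- labels[keep]
  clusters <- unique(labels)
  means <- t(vapply(clusters, function(cl) {
    colMeans(scores[labels == cl, , drop = FALSE])
  }, numeric(ncol(scores))))
  dimnames(means) <- list(clusters, colnames(scores))
  if (zscore) {
    z <- apply(means, 2L, function(v) {
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    if (is.null(dim(z))) z <- matrix(z, nrow = nrow(means), dimnames = dimnames(means))
    attr(means, "zscores") <- z
  }
  means
}

#' Normalize a score series to a baseline
#'
#' Subtracts (default) or divides by the mean score of the baseline group —
#' e.g. expressing each later time point relative to the first.
#'
#' @param score_series numeric vector of scores.
#' @param group per-score group key (e.g. time point).
#' @param baseline_key group serving as baseline.
#' @param mode `"difference"` or `"ratio"`; ratio errors on a non-positive
#'   baseline mean.
#' @return normalized numeric vector, same order and names.
#' @export
normalize_to_baseline <- function(score_series, group, baseline_key,
                                  mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  if (length(group) != length(score_series)) stopf("group length mismatch")
  if (!baseline_key %in% group) stopf("baseline '%s' absent from the series", baseline_key)
  base <- mean(score_series[group == baseline_key])
  if (mode == "difference") {
    score_series - base
  } else {
    if (base <= 0) stopf("ratio mode needs a positive baseline mean (got %g)", base)
    score_series / base
  }
}
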