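## Preranked gene-set enrichment: the weighted running-sum (KS-like) walk,
## a gene-set permutation null with exhaustive enumeration for small
## problems, batch testing with BH adjustment, and overlap-coefficient
## graph clustering of significant sets into themes.

## Order a named statistic vector descending; ties broken by gene id so the
## ranked list is deterministic.
.order_ranked <- function(stats_vec) {
  if (is.null(names(stats_vec))) stopf("the ranked statistic vector must be named")
  if (anyDuplicated(names(stats_vec))) stopf("duplicate gene ids in the ranked list")
  if (any(!is.finite(stats_vec))) stopf("ranking statistics must be finite")
  stats_vec[order(-stats_vec, names(stats_vec), method = "radix")]
}

## Fast ES from sorted hit positions: the running sum attains its maximum
## immediately after a hit and its minimum immediately before one.
.es_from_positions <- function(abs_stats, idx, weight_p, N) {
  n <- length(idx)
  w <- abs_stats[idx]^weight_p
  sw <- sum(w)
  if (sw == 0) w[] <- 1 / n else w <- w / sw
  H <- cumsum(w)
  miss <- 1 / (N - n)
  after <- H - (idx - seq_len(n)) * miss
  before <- c(0, H[-n]) - (idx - seq_len(n)) * miss
  es_pos <- max(after)
  es_neg <- min(c(before, 0))
  if (abs(es_pos) >= abs(es_neg) - 1e-12) es_pos else es_neg
}

#' Weighted enrichment score of a gene set in a ranked list
#'
#' Walks down the list (statistics sorted descending): a set member
#' increments the running sum by its weighted statistic share
#' `|s|^p / sum_set |s|^p`, a non-member decrements by `1/(N - n_set)`.
#' The ES is the running-sum extremum with the larger absolute value
#' (positive chosen on an exact tie).
#'
#' @param ranked named numeric vector of per-gene statistics (sorted
#'   internally, descending, ties broken by id).
#' @param gene_set character vector of member ids.
#' @param weight_p weighting exponent (1 = classic weighted; 0 =
#'   unweighted, hand-checkable).
#' @return list with `es`, `running_sum` (length N), `hit_positions`,
#'   `leading_edge` (member ids up to / from the extremum).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  ranked <- .order_ranked(ranked)
  N <- length(ranked)
  hits <- names(ranked) %in% gene_set
  n <- sum(hits)
  if (n == 0L) stopf("no gene-set member present in the ranked list")
  if (n == N) stopf("gene set covers the entire ranked universe")
  w <- abs(ranked)^weight_p
  w[!hits] <- 0
  sw <- sum(w)
  incr <- if (sw == 0) hits / n else w / sw
  decr <- (!hits) / (N - n)
  running <- unname(cumsum(incr - decr))
  i_max <- which.max(running); i_min <- which.min(running)
  ## positive extremum wins exact ties; |ES| <= 1 so an absolute epsilon
  ## absorbs accumulation noise in the tie comparison
  es <- if (abs(running[i_max]) >= abs(running[i_min]) - 1e-12) {
    running[i_max]
  } else {
    running[i_min]
  }
  leading <- if (es >= 0) {
    names(ranked)[seq_len(i_max)][hits[seq_len(i_max)]]
  } else {
    names(ranked)[i_min:N][hits[i_min:N]]
  }
  list(es = es, running_sum = running,
       hit_positions = which(hits), leading_edge = leading)
}

#' Permutation test for an enrichment score
#'
#' The null is random same-size gene sets drawn from the ranked universe.
#' When `choose(N, n_set) <= exhaustive_limit` every placement is
#' enumerated and the p-value is the plain signed-tail proportion over all
#' placements; otherwise `n_perm` Monte-Carlo draws are used with the
#' add-one estimator `(1 + b) / (1 + n_perm)`. NES is the observed ES
#' divided by the mean |ES| of the same-sign null scores.
#'
#' @param ranked named statistic vector.
#' @param gene_set member ids.
#' @param n_perm Monte-Carlo permutations (>= 100 recommended for
#'   reporting).
#' @param seed integer seed for the permutation stream.
#' @param weight_p weighting exponent.
#' @param exhaustive_limit enumerate all placements when the number of
#'   distinct same-size sets is at most this.
#' @return list with `es`, `nes`, `p`, `n_null`, `mode`
#'   ("exhaustive"/"montecarlo"), `leading_edge`.
#' @export
permutation_test <- function(ranked, gene_set, n_perm = 1000, seed = 1,
                             weight_p = 1, exhaustive_limit = 10000) {
  ranked <- .order_ranked(ranked)
  N <- length(ranked)
  obs <- enrichment_score(ranked, gene_set, weight_p)
  n <- length(obs$hit_positions)
  abs_stats <- abs(ranked)
  n_comb <- suppressWarnings(choose(N, n))
  if (is.finite(n_comb) && n_comb <= exhaustive_limit) {
    combs <- utils::combn(N, n)
    null_es <- apply(combs, 2L, function(idx)
      .es_from_positions(abs_stats, idx, weight_p, N))
    p <- if (obs$es >= 0) mean(null_es >= obs$es) else mean(null_es <= obs$es)
    mode <- "exhaustive"
  } else {
    null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      .es_from_positions(abs_stats, sort(sample.int(N, n)), weight_p, N)
    }, numeric(1)))
    b <- if (obs$es >= 0) sum(null_es >= obs$es) else sum(null_es <= obs$es)
    p <- (1 + b) / (1 + length(null_es))
    mode <- "montecarlo"
  }
  if (length(unique(null_es)) == 1L) warnf("degenerate permutation null: all null ES equal")
  same_sign <- if (obs$es >= 0) null_es[null_es > 0] else null_es[null_es < 0]
  nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
  list(es = obs$es, nes = nes, p = p, n_null = length(null_es), mode = mode,
       leading_edge = obs$leading_edge)
}

#' Batch gene-set enrichment over a collection
#'
#' @param ranked named statistic vector.
#' @param collection a `gene_set_collection` (or named list of id vectors).
#' @param min_size,max_size bounds on the set size after intersection with
#'   the universe; out-of-bounds sets are skipped and logged.
#' @param n_perm,seed,weight_p passed to [permutation_test()]; each set's
#'   permutation stream is derived deterministically from `seed`.
#' @return data.frame with columns `set`, `size`, `es`, `nes`, `pval`,
#'   `padj`, `leading_edge` (comma-joined); skipped sets are recorded in
#'   the `skipped` attribute.
#' @export
gsea_batch <- function(ranked, collection, min_size = 5, max_size = 500,
                       n_perm = 1000, seed = 1, weight_p = 1) {
  if (length(collection) == 0L) stopf("empty gene-set collection")
  ranked <- .order_ranked(ranked)
  universe <- names(ranked)
  sizes <- vapply(collection, function(s) length(intersect(s, universe)), integer(1))
  ## a set covering the whole universe has no non-members to walk against
  keep <- sizes >= min_size & sizes <= min(max_size, length(universe) - 1L)
  skipped <- names(collection)[!keep]
  if (length(skipped)) {
    message(sprintf("skipping %d set(s) outside size bounds [%d, %d]: %s",
                    length(skipped), min_size, max_size,
                    paste(utils::head(skipped, 10L), collapse = ", ")))
  }
  if (!any(keep)) stopf("no gene set within the size bounds")
  kept <- names(collection)[keep]
  rows <- lapply(seq_along(kept), function(i) {
    pt <- permutation_test(ranked, collection[[kept[i]]], n_perm = n_perm,
                           seed = child_seed(seed, i), weight_p = weight_p)
    data.frame(set = kept[i], size = sizes[[kept[i]]], es = pt$es, nes = pt$nes,
               pval = pt$p, leading_edge = paste(pt$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- adjust_bh(out$pval)
  out <- out[, c("set", "size", "es", "nes", "pval", "padj", "leading_edge")]
  attr(out, "skipped") <- skipped
  out
}

#' Overlap coefficient of two sets
#'
#' `|A intersect B| / min(|A|, |B|)`.
#'
#' @param set_a,set_b non-empty character vectors.
#' @return value in [0, 1].
#' @export
overlap_coefficient <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L) stopf("overlap coefficient of an empty set")
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' Cluster gene sets by overlap-coefficient connectivity
#'
#' Builds the weighted graph whose edges connect set pairs with overlap
#' coefficient at or above `threshold`, and labels its connected
#' components; each component is summarized by its member union — the
#' "theme" the component represents.
#'
#' @param collection named list of gene sets.
#' @param threshold overlap-coefficient floor in [0, 1].
#' @return list with `edges` (data.frame from, to, weight), `components`
#'   (named integer membership), `summaries` (per component: sets, size of
#'   the gene union, union genes).
#' @export
gene_set_components <- function(collection, threshold) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stopf("threshold must lie in [0, 1] (got %s)", format(threshold))
  }
  nms <- names(collection)
  if (is.null(nms)) stopf("gene sets must be named")
  k <- length(collection)
  from <- character(); to <- character(); wt <- numeric()
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        oc <- overlap_coefficient(collection[[i]], collection[[j]])
        if (oc >= threshold) {
          from <- c(from, nms[i]); to <- c(to, nms[j]); wt <- c(wt, oc)
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = wt, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nms, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  summaries <- lapply(sort(unique(comp)), function(ci) {
    members <- nms[comp == ci]
    union_genes <- sort(unique(unlist(collection[members], use.names = FALSE)))
    list(sets = members, n_genes = length(union_genes), genes = union_genes)
  })
  list(edges = data.frame(from = from, to = to, weight = wt, stringsAsFactors = FALSE),
       components = comp, summaries = summaries)
}
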