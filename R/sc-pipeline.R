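## Single-cell stage: QC metrics and filtering, median-scaled
## log-normalization, HVG selection, PCA, kNN-Jaccard graph construction,
## Louvain clustering, pseudobulking and pseudobulk DE (through the bulk
## engine with donor as a fixed-effect covariate), and CLR normalization
## for antibody-derived tag counts. Single-cell matrices are cells x genes.

#' Per-cell QC metrics
#'
#' @param cells cells x genes count matrix.
#' @param mito_prefix gene-name prefixes identifying mitochondrial genes.
#' @return data.frame with `total_counts`, `detected_genes`,
#'   `mito_fraction` per cell.
#' @export
cell_qc_metrics <- function(cells, mito_prefix = c("mt-", "MT-")) {
  check_count_matrix(cells, what = "cells")
  total <- rowSums(cells)
  detected <- rowSums(cells > 0)
  pat <- paste0("^(", paste(mito_prefix, collapse = "|"), ")")
  mito_genes <- grepl(pat, colnames(cells))
  mito <- if (any(mito_genes)) rowSums(cells[, mito_genes, drop = FALSE]) else rep(0, nrow(cells))
  data.frame(total_counts = total, detected_genes = detected,
             mito_fraction = ifelse(total > 0, mito / total, 0),
             row.names = rownames(cells))
}

#' QC-filter cells
#'
#' Removes cells with mitochondrial fraction at or above `mito_max`
#' (inclusive boundary), and cells whose total counts or detected genes
#' fall strictly below the `count_quantile`-th quantile (type-7, linear
#' interpolation) of the respective distribution.
#'
#' @param cells cells x genes count matrix.
#' @param mito_max mitochondrial-fraction ceiling (inclusive removal);
#'   NULL disables the filter.
#' @param count_quantile quantile floor for totals/detected genes; NULL
#'   disables.
#' @param mito_prefix mitochondrial gene-name prefixes.
#' @return filtered matrix with a `removed` attribute (data.frame of cell,
#'   reason).
#' @export
qc_filter_cells <- function(cells, mito_max = 0.20, count_quantile = 0.10,
                            mito_prefix = c("mt-", "MT-")) {
  qc <- cell_qc_metrics(cells, mito_prefix)
  removed <- data.frame(cell = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(cells))
  if (!is.null(mito_max)) {
    pat <- paste0("^(", paste(mito_prefix, collapse = "|"), ")")
    if (!any(grepl(pat, colnames(cells)))) {
      stopf("mitochondrial filter requested but no gene matches prefix(es): %s",
            paste(mito_prefix, collapse = ", "))
    }
    hit <- qc$mito_fraction >= mito_max
    removed <- rbind(removed, data.frame(cell = rownames(cells)[hit],
                                         reason = "mito_fraction",
                                         stringsAsFactors = FALSE))
    drop <- drop | hit
  }
  if (!is.null(count_quantile)) {
    for (metric in c("total_counts", "detected_genes")) {
      cut <- stats::quantile(qc[[metric]], count_quantile, type = 7, names = FALSE)
      hit <- qc[[metric]] < cut & !drop
      if (any(hit)) {
        removed <- rbind(removed, data.frame(cell = rownames(cells)[hit],
                                             reason = metric,
                                             stringsAsFactors = FALSE))
      }
      drop <- drop | (qc[[metric]] < cut)
    }
  }
  if (all(drop)) stopf("QC removed every cell")
  out <- cells[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Median-scaled log-normalization
#'
#' Size factor = cell total / median of totals; normalized value =
#' `log2(count / size_factor + 1)`. Doubling a cell's counts leaves its
#' normalized profile unchanged.
#'
#' @param cells cells x genes count matrix with positive totals.
#' @return cells x genes matrix of log-normalized values with a
#'   `size_factors` attribute.
#' @export
lognormalize_cells <- function(cells) {
  total <- rowSums(cells)
  if (any(total <= 0)) {
    stopf("zero-total cell(s) (QC should remove them first): %s",
          paste(utils::head(rownames(cells)[total <= 0], 5L), collapse = ", "))
  }
  sf <- total / stats::median(total)
  out <- log2(cells / sf + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Select highly variable genes
#'
#' Top-`n` genes by variance of the normalized values; ties broken
#' deterministically by gene id.
#'
#' @param normalized cells x genes matrix.
#' @param n number of genes to select.
#' @return character vector of gene ids, length `min(n, #genes)`.
#' @export
select_hvgs <- function(normalized, n = 2000) {
  v <- apply(normalized, 2L, stats::var)
  ord <- order(-v, colnames(normalized), method = "radix")
  colnames(normalized)[ord][seq_len(min(n, ncol(normalized)))]
}

#' PCA embedding of cells
#'
#' Gene-centred PCA on the HVG submatrix. The result is deterministic: each
#' component's sign is fixed so that its largest-magnitude gene loading is
#' positive.
#'
#' @param normalized cells x genes matrix.
#' @param hvgs genes to use (default: all).
#' @param n_components dimensions to keep.
#' @return cells x components coordinate matrix with a
#'   `variance_fraction` attribute.
#' @export
pca_cells <- function(normalized, hvgs = colnames(normalized), n_components = 30) {
  m <- normalized[, hvgs, drop = FALSE]
  n_components <- min(n_components, nrow(m) - 1L, ncol(m))
  if (n_components < 1L) stopf("degenerate matrix: cannot extract any component")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
    if (flip < 0) coords[, j] <- -coords[, j]
  }
  attr(coords, "variance_fraction") <- pc$sdev^2 / sum(pc$sdev^2)
  coords
}

#' Shared-nearest-neighbour Jaccard graph
#'
#' Each cell's `k` nearest Euclidean neighbours (self excluded; distance
#' ties broken by cell index) define neighbour sets; an undirected edge
#' joins i and j when either is in the other's set, weighted by the
#' Jaccard similarity of the two neighbour sets. Zero-weight edges are
#' dropped.
#'
#' @param embedding cells x dims coordinate matrix.
#' @param k neighbours per cell (`k < n_cells`).
#' @return an igraph undirected weighted graph with one vertex per cell.
#' @export
knn_jaccard_graph <- function(embedding, k = 9) {
  n <- nrow(embedding)
  if (k >= n) stopf("k = %d must be smaller than the number of cells (%d)", k, n)
  D <- as.matrix(stats::dist(embedding))
  nbrs <- lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n), method = "radix")
    ord <- ord[ord != i]
    ord[seq_len(k)]
  })
  ## candidate edges: (i, j) whenever j is in i's neighbour set (either
  ## direction), normalized to i < j and de-duplicated
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(pmin(i, nbrs[[i]]), pmax(i, nbrs[[i]]))
  }))
  pairs <- unique(pairs)
  wt <- vapply(seq_len(nrow(pairs)), function(e) {
    a <- nbrs[[pairs[e, 1L]]]; b <- nbrs[[pairs[e, 2L]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  keep <- wt > 0
  from <- pairs[keep, 1L]; to <- pairs[keep, 2L]; wt <- wt[keep]
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[from], to = ids[to], weight = wt),
    directed = FALSE,
    vertices = data.frame(name = ids))
  g
}

#' Louvain community detection
#'
#' Greedy multi-level modularity optimization on the weighted graph; the
#' node visiting order is seeded, so labels are reproducible. Disconnected
#' components are handled independently by the algorithm.
#'
#' @param graph an igraph graph (e.g. from [knn_jaccard_graph()]).
#' @param resolution modularity resolution parameter.
#' @param seed integer seed.
#' @return named integer vector of cluster labels (contiguous from 1) with
#'   a `modularity` attribute.
#' @export
louvain_communities <- function(graph, resolution = 1.0, seed = 1) {
  if (igraph::vcount(graph) == 0L) stopf("empty graph")
  comm <- with_seed(seed, igraph::cluster_louvain(graph, resolution = resolution))
  labels <- igraph::membership(comm)
  out <- stats::setNames(as.integer(factor(labels)), names(labels))
  attr(out, "modularity") <- max(igraph::modularity(comm))
  out
}

#' Full clustering pass over a cell matrix
#'
#' QC filter, log-normalization, HVG selection, PCA, kNN-Jaccard graph and
#' Louvain, returning every intermediate.
#'
#' @param cells cells x genes count matrix.
#' @param n_hvgs,n_components,k,resolution,seed stage parameters.
#' @param mito_max,count_quantile,mito_prefix QC parameters (see
#'   [qc_filter_cells()]).
#' @return list with `cells` (retained), `normalized`, `hvgs`, `embedding`,
#'   `graph`, `clusters`.
#' @export
cluster_cells <- function(cells, n_hvgs = 2000, n_components = 30, k = 9,
                          resolution = 1.0, seed = 1, mito_max = 0.20,
                          count_quantile = 0.10, mito_prefix = c("mt-", "MT-")) {
  kept <- qc_filter_cells(cells, mito_max, count_quantile, mito_prefix)
  normalized <- lognormalize_cells(kept)
  hvgs <- select_hvgs(normalized, n_hvgs)
  embedding <- pca_cells(normalized, hvgs, n_components)
  graph <- knn_jaccard_graph(embedding, k)
  clusters <- louvain_communities(graph, resolution, seed)
  list(cells = kept, normalized = normalized, hvgs = hvgs,
       embedding = embedding, graph = graph, clusters = clusters[rownames(kept)])
}

#' Pseudobulk cells into group-level count columns
#'
#' Integer column sums per group (e.g. cluster x sample); groups with
#' fewer than `min_cells` cells are removed. The output is genes x groups,
#' the bulk orientation, directly consumable by the DE engine.
#'
#' @param cells cells x genes count matrix.
#' @param groups factor/character vector or data.frame of factors (one row
#'   per cell); data.frame columns are combined with ".".
#' @param min_cells per-group cell floor (strictly-below groups dropped).
#' @return list with `counts` (genes x groups), `cell_counts` (per group),
#'   `meta` (one row per retained group with the grouping factor values).
#' @export
pseudobulk <- function(cells, groups, min_cells = 10) {
  if (is.data.frame(groups)) {
    key <- do.call(paste, c(groups, sep = "."))
    meta_cols <- groups
  } else {
    key <- as.character(groups)
    meta_cols <- data.frame(group = key, stringsAsFactors = FALSE)
  }
  if (length(key) != nrow(cells)) stopf("grouping covers %d cells but matrix has %d",
                                        length(key), nrow(cells))
  tab <- table(key)
  keep_groups <- names(tab)[tab >= min_cells]
  if (length(keep_groups) == 0L) {
    stopf("no group reaches the %d-cell floor (largest has %d)", min_cells, max(tab))
  }
  dropped <- setdiff(names(tab), keep_groups)
  if (length(dropped)) {
    message(sprintf("dropping %d pseudobulk group(s) below %d cells: %s",
                    length(dropped), min_cells, paste(dropped, collapse = ", ")))
  }
  counts <- vapply(keep_groups, function(g) {
    as.integer(colSums(cells[key == g, , drop = FALSE]))
  }, integer(ncol(cells)))
  rownames(counts) <- colnames(cells)
  meta <- meta_cols[match(keep_groups, key), , drop = FALSE]
  rownames(meta) <- keep_groups
  list(counts = counts,
       cell_counts = stats::setNames(as.integer(tab[keep_groups]), keep_groups),
       meta = meta)
}

#' Pseudobulk differential expression between two cluster levels
#'
#' Runs the bulk engine (low-expression filter, TMM, precision weights,
#' moderated fit, threshold test, BH) on pseudobulk columns, with donor
#' included as a fixed-effect covariate to absorb between-donor shifts.
#'
#' @param pb a [pseudobulk()] result whose `meta` has a `cluster` column
#'   (and optionally `donor`).
#' @param cluster_a,cluster_b the two cluster levels to contrast (a minus
#'   b).
#' @param fc_threshold TREAT floor; 1 gives the plain moderated t.
#' @param fdr FDR level for directional calls.
#' @return a `de_result` with a `directions` attribute.
#' @export
pseudobulk_de <- function(pb, cluster_a, cluster_b, fc_threshold = 1,
                          fdr = 0.05) {
  meta <- pb$meta
  if (!"cluster" %in% names(meta)) stopf("pseudobulk metadata lacks a 'cluster' column")
  sel <- meta$cluster %in% c(cluster_a, cluster_b)
  if (sum(meta$cluster[sel] == cluster_a) < 2L ||
      sum(meta$cluster[sel] == cluster_b) < 2L) {
    stopf("need >= 2 pseudobulk groups per contrast level")
  }
  counts <- pb$counts[, sel, drop = FALSE]
  meta <- meta[sel, , drop = FALSE]
  cluster <- factor(meta$cluster, levels = c(cluster_b, cluster_a))
  if ("donor" %in% names(meta) && length(unique(meta$donor)) > 1L) {
    donor <- factor(meta$donor)
    design <- stats::model.matrix(~ cluster + donor)
  } else {
    design <- stats::model.matrix(~ cluster)
  }
  if (qr(design)$rank < ncol(design)) {
    stopf("confounded design: donor aliases the cluster contrast")
  }
  counts <- filter_low_expression(counts, as.character(cluster))
  f <- tmm_factors(counts)
  lc <- log_cpm(counts, f)
  w <- mean_variance_weights(lc, design)
  cm <- matrix(0, ncol(design), 1, dimnames = list(colnames(design), "cluster_a_vs_b"))
  cm[2L, 1L] <- 1
  fits <- fit_and_moderate(lc, w, design, contrasts = cm)
  res <- treat_test(fits, "cluster_a_vs_b", fc_threshold = fc_threshold)
  attr(res, "directions") <- decide_directions(res, fdr)
  res
}

#' Centred log-ratio normalization of protein-tag counts
#'
#' Per cell: `v_i = ln(x_i + pseudo) - mean_j ln(x_j + pseudo)`; values sum
#' to zero within each cell.
#'
#' @param protein_counts cells x proteins count matrix.
#' @param pseudo pseudocount.
#' @return cells x proteins matrix of CLR values.
#' @export
clr_normalize_protein <- function(protein_counts, pseudo = 1) {
  if (any(protein_counts < 0)) stopf("protein counts must be non-negative")
  lg <- log(protein_counts + pseudo)
  out <- lg - rowMeans(lg)
  dimnames(out) <- dimnames(protein_counts)
  out
}
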