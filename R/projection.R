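## Projection of derived signatures onto external-style datasets:
## pseudobulk-then-score workflows, per-cell selection of T_FH-like cells,
## spatial region scoring, and dominance summaries.

#' Pseudobulk a dataset and score it against signatures
#'
#' Cells are pseudobulked on the grouping factors, lowly expressed genes
#' removed, TMM-normalized log-CPM computed, and every pseudobulk column
#' rank-scored against every signature (upregulated genes only by
#' default, matching how external datasets are projected).
#'
#' @param counts cells x genes count matrix.
#' @param metadata per-cell data.frame (row names = cell ids).
#' @param signatures named list of `gene_signature`s / gene-id vectors.
#' @param group_by metadata column(s) defining the pseudobulk groups.
#' @param min_cells per-group cell floor.
#' @param use `"up_only"` or `"bidirectional"`.
#' @return object of class `projection_result`: `scores`
#'   (pseudosamples x signatures), `groups` (pseudobulk metadata incl.
#'   cell counts), `dominance` (per pseudosample argmax table), and the
#'   signature names used.
#' @export
project_signatures <- function(counts, metadata, signatures, group_by,
                               min_cells = 10, use = "up_only") {
  missing_cols <- setdiff(group_by, names(metadata))
  if (length(missing_cols)) stopf("metadata lacks grouping column(s): %s",
                                  paste(missing_cols, collapse = ", "))
  metadata <- metadata[rownames(counts), , drop = FALSE]
  pb <- pseudobulk(counts, metadata[, group_by, drop = FALSE], min_cells = min_cells)
  filt <- filter_low_expression(pb$counts, pb$meta[[group_by[1L]]])
  f <- tmm_factors(filt)
  lc <- log_cpm(filt, f)
  scores <- score_matrix(lc, signatures, use = use)
  groups <- cbind(pb$meta, n_cells = pb$cell_counts)
  dom <- dominance_summary(scores)
  structure(list(scores = scores, groups = groups, dominance = dom,
                 signatures = colnames(scores), use = use),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection_result: %d pseudosample(s) x %d signature(s) (%s)\n",
              nrow(x$scores), ncol(x$scores), x$use))
  invisible(x)
}

#' Select T_FH-like cells by bidirectional core score
#'
#' Restricts to cells whose annotation is allowed, scores each cell with
#' the bidirectional core signature, and keeps cells with a strictly
#' positive total score.
#'
#' @param cells cells x genes count matrix.
#' @param core_signature a `gene_signature` with non-empty up and down
#'   sets.
#' @param annotations per-cell annotation labels (NULL to skip the
#'   annotation filter).
#' @param allowed_annotations labels to retain (required when
#'   `annotations` is given; must be non-empty).
#' @return character vector of selected cell ids, with the per-cell score
#'   vector as the `scores` attribute.
#' @export
select_tfh_like <- function(cells, core_signature, annotations = NULL,
                            allowed_annotations = NULL) {
  stopifnot(inherits(core_signature, "gene_signature"))
  if (length(core_signature$up) == 0L || length(core_signature$down) == 0L) {
    stopf("T_FH-like selection needs both up and down core gene sets")
  }
  ids <- rownames(cells)
  if (!is.null(annotations)) {
    if (is.null(allowed_annotations) || length(allowed_annotations) == 0L) {
      stopf("allowed_annotations must be non-empty when annotations are supplied")
    }
    keep <- annotations %in% allowed_annotations
    if (!any(keep)) stopf("no cell carries an allowed annotation")
    cells <- cells[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  sc <- score_matrix(t(cells), list(core = core_signature), use = "bidirectional")
  total <- stats::setNames(sc[, "core"], ids)
  selected <- ids[total > 0]
  attr(selected, "scores") <- total
  selected
}

#' Score spatial spots and summarize by region
#'
#' Every spot is scored against every signature; labelled regions are
#' summarized by mean and median, unlabelled spots separately as
#' background.
#'
#' @param spatial a `spatial_sim` or a list with `counts` (spots x genes)
#'   and `region` (label per spot, NA outside any region).
#' @param signatures named signature list.
#' @param use `"up_only"` or `"bidirectional"`.
#' @param min_coverage minimal fraction of each signature's up genes that
#'   must be present in the panel.
#' @return list with `spot_scores` (spots x signatures), `region_summary`
#'   (data.frame region x signature mean/median/n, background row
#'   included), `regions` (labels used).
#' @export
score_regions <- function(spatial, signatures, use = "up_only",
                          min_coverage = 0.25) {
  counts <- spatial$counts
  region <- spatial$region
  if (is.null(counts) || is.null(region)) stopf("spatial dataset needs counts and region labels")
  sigs <- .as_signature_list(signatures)
  panel <- colnames(counts)
  for (nm in names(sigs)) {
    cov <- mean(sigs[[nm]]$up %in% panel)
    if (cov < min_coverage) {
      stopf("signature '%s': only %.0f%% of up genes on the panel (floor %.0f%%)",
            nm, 100 * cov, 100 * min_coverage)
    }
    if (cov < 1) warnf("signature '%s': %.0f%% of up genes on the panel", nm, 100 * cov)
  }
  spot_scores <- suppressWarnings(score_matrix(t(counts), signatures, use = use))
  lab <- ifelse(is.na(region), "background", region)
  groups <- unique(lab)
  rows <- lapply(groups, function(g) {
    m <- spot_scores[lab == g, , drop = FALSE]
    data.frame(region = g, signature = colnames(m),
               mean = colMeans(m),
               median = apply(m, 2L, stats::median),
               n_spots = nrow(m), stringsAsFactors = FALSE, row.names = NULL)
  })
  list(spot_scores = spot_scores,
       region_summary = do.call(rbind, rows),
       regions = setdiff(groups, "background"))
}

#' Dominance summary of a score matrix
#'
#' Per row (group): the argmax signature, the margin to the runner-up, the
#' full rank vector, and a tie flag naming all tied maxima.
#'
#' @param scores groups x signatures score matrix (>= 2 signatures).
#' @return data.frame with columns `group`, `dominant`, `margin`, `tie`,
#'   `ranking` (comma-joined, best first).
#' @export
dominance_summary <- function(scores) {
  if (ncol(scores) < 2L) stopf("dominance needs at least two signatures")
  sig_names <- colnames(scores)
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    v <- scores[i, ]
    ord <- order(-v, sig_names, method = "radix")
    top <- v[ord[1L]]; second <- v[ord[2L]]
    tied <- sig_names[v == top]
    data.frame(group = rownames(scores)[i] %||% as.character(i),
               dominant = if (length(tied) > 1L) paste(sort(tied), collapse = "|")
                          else sig_names[ord[1L]],
               margin = top - second,
               tie = length(tied) > 1L,
               ranking = paste(sig_names[ord], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
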