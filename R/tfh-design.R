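## Study-design helpers binding the DE engine to the multi-infection sorted
## T cell layout: one group-means model over condition x celltype, with the
## contrast families every signature rule needs.

#' Build the design and contrast matrices for a multi-condition sorted
#' T cell experiment
#'
#' One coefficient per condition x celltype group (group-means
#' parameterization). The returned contrast matrix covers, per condition:
#' T_FH vs T_eff, T_FR vs T_FH, T_FR vs T_eff, and one-vs-rest contrasts of
#' T_FH and T_eff across conditions; plus the combined T_FH vs T_eff
#' contrast averaging the celltype effect over all conditions.
#'
#' @param samples data.frame with `condition` and `celltype` columns, one
#'   row per sample (row names = sample ids).
#' @param tfh_levels celltype levels pooled into the T_FH population.
#' @param tfr_level,teff_level celltype labels of the regulatory and
#'   effector populations.
#' @param pool_il21 pool the IL-21+ and IL-21- T_FH subsets (averaged with
#'   equal weight) into one T_FH population; with `FALSE`, only the first
#'   element of `tfh_levels` is used.
#' @return list with `design` (samples x groups), `contrasts`
#'   (groups x contrasts) and `families` (named list mapping each contrast
#'   family to its contrast column names, indexed by condition).
#' @export
tfh_design <- function(samples,
                       tfh_levels = c("tfh_il21pos", "tfh_il21neg"),
                       tfr_level = "tfr", teff_level = "teff",
                       pool_il21 = TRUE) {
  for (col in c("condition", "celltype")) {
    if (!col %in% names(samples)) stopf("samples table lacks a '%s' column", col)
  }
  if (!pool_il21) tfh_levels <- tfh_levels[1L]
  conds <- unique(as.character(samples$condition))
  group <- factor(paste(samples$condition, samples$celltype, sep = "."),
                  levels = unique(paste(rep(conds, each = length(unique(samples$celltype))),
                                        unique(samples$celltype), sep = ".")))
  group <- droplevels(group)
  design <- stats::model.matrix(~ 0 + group)
  colnames(design) <- levels(group)
  rownames(design) <- rownames(samples)

  unit <- function(cond, celltypes) {
    v <- stats::setNames(numeric(ncol(design)), colnames(design))
    keys <- paste(cond, celltypes, sep = ".")
    present <- keys %in% names(v)
    if (!all(present)) stopf("group(s) absent from design: %s",
                             paste(keys[!present], collapse = ", "))
    v[keys] <- 1 / length(keys)
    v
  }
  tfh <- function(cond) unit(cond, tfh_levels)
  one <- function(cond, ct) unit(cond, ct)

  cmat <- list()
  for (cond in conds) {
    cmat[[paste0("tfh_vs_teff.", cond)]] <- tfh(cond) - one(cond, teff_level)
    cmat[[paste0("tfr_vs_tfh.", cond)]] <- one(cond, tfr_level) - tfh(cond)
    cmat[[paste0("tfr_vs_teff.", cond)]] <- one(cond, tfr_level) - one(cond, teff_level)
  }
  cmat[["tfh_vs_teff.combined"]] <-
    Reduce(`+`, lapply(conds, function(cd) tfh(cd) - one(cd, teff_level))) / length(conds)
  if (length(conds) >= 2L) {
    for (cond in conds) {
      rest <- setdiff(conds, cond)
      rest_tfh <- Reduce(`+`, lapply(rest, tfh)) / length(rest)
      rest_teff <- Reduce(`+`, lapply(rest, function(cd) one(cd, teff_level))) / length(rest)
      cmat[[paste0("tfh_onevrest.", cond)]] <- tfh(cond) - rest_tfh
      cmat[[paste0("teff_onevrest.", cond)]] <- one(cond, teff_level) - rest_teff
    }
  }
  contrasts <- do.call(cbind, cmat)
  fam <- function(prefix) {
    nm <- grep(paste0("^", prefix, "\\."), colnames(contrasts), value = TRUE)
    nm <- nm[nm != paste0(prefix, ".combined")]
    stats::setNames(nm, sub(paste0("^", prefix, "\\."), "", nm))
  }
  list(design = design, contrasts = contrasts,
       families = list(
         tfh_vs_teff = fam("tfh_vs_teff"),
         tfh_vs_teff_combined = "tfh_vs_teff.combined",
         tfr_vs_tfh = fam("tfr_vs_tfh"),
         tfr_vs_teff = fam("tfr_vs_teff"),
         tfh_onevrest = fam("tfh_onevrest"),
         teff_onevrest = fam("teff_onevrest")
       ),
       conditions = conds)
}

#' Run the full bulk differential-expression pipeline
#'
#' Library-size filter, low-expression filter (grouped by
#' condition x celltype), TMM normalization, log-CPM, mean-variance
#' precision weights, moderated weighted fits, a TREAT test per contrast,
#' BH adjustment and directional calls.
#'
#' @param counts genes x samples integer matrix.
#' @param samples metadata with `condition` and `celltype`, row names
#'   matching `colnames(counts)`.
#' @param fc_threshold TREAT fold-change floor (default 1.1).
#' @param fdr FDR level for directional calls (boundary inclusive).
#' @param min_reads library-size floor (strictly-below samples dropped).
#' @param ... passed to [tfh_design()].
#' @return object of class `tfh_de`: the fitted model, one `de_result` per
#'   contrast, the genes x contrasts matrix of directional calls, the
#'   normalized log-CPM matrix and the design description.
#' @export
run_bulk_de <- function(counts, samples, fc_threshold = 1.1, fdr = 0.05,
                        min_reads = 1e6, ...) {
  assert_valid_dataset(counts, samples, required_factors = c("condition", "celltype"))
  counts <- filter_samples_by_library_size(counts, min_reads)
  samples <- samples[colnames(counts), , drop = FALSE]
  groups <- paste(samples$condition, samples$celltype, sep = ".")
  counts <- filter_low_expression(counts, groups)
  dsn <- tfh_design(samples, ...)
  f <- tmm_factors(counts)
  lc <- log_cpm(counts, f)
  w <- mean_variance_weights(lc, dsn$design)
  fits <- fit_and_moderate(lc, w, dsn$design, contrasts = dsn$contrasts)
  results <- lapply(colnames(dsn$contrasts), function(cn) {
    treat_test(fits, cn, fc_threshold = fc_threshold)
  })
  names(results) <- colnames(dsn$contrasts)
  directions <- vapply(results, decide_directions, fdr = fdr,
                       integer(nrow(fits$effects)))
  rownames(directions) <- rownames(fits$effects)
  structure(list(
    fits = fits, results = results, directions = directions,
    logcpm = lc, norm_factors = f, samples = samples,
    families = dsn$families, conditions = dsn$conditions,
    params = list(fc_threshold = fc_threshold, fdr = fdr, min_reads = min_reads)
  ), class = "tfh_de")
}

#' @export
print.tfh_de <- function(x, ...) {
  cat(sprintf("tfh_de: %d genes x %d samples, %d contrasts (TREAT FC %.3g, FDR %.3g)\n",
              nrow(x$directions), nrow(x$samples), ncol(x$directions),
              x$params$fc_threshold, x$params$fdr))
  up <- colSums(x$directions == 1L); dn <- colSums(x$directions == -1L)
  for (nm in names(up)) cat(sprintf("  %-28s up %5d  down %5d\n", nm, up[nm], dn[nm]))
  invisible(x)
}
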