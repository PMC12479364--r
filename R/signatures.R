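## Consensus signature-derivation rules over directional DE calls: the core
## T_FH signature (same-direction calls in >= 3 of 5 infections plus the
## combined contrast), the T_FR signature (consensus in both T_FR contrast
## families), per-pathogen context signatures from one-vs-rest contrasts,
## and the descriptive machinery around them (UpSet-style intersections,
## four-group core partition, annotation flags, heatmap z-scores).

new_gene_signature <- function(name, up, down = character(), provenance = list()) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  overlap <- intersect(up, down)
  if (length(overlap)) {
    stopf("signature '%s' has gene(s) in both directions: %s", name,
          paste(overlap, collapse = ", "))
  }
  structure(list(name = name, up = up, down = down, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up, %d down (rule: %s)\n",
              x$name, length(x$up), length(x$down),
              x$provenance$rule %||% "unspecified"))
  invisible(x)
}

## Shared gene universe check for a calls matrix (genes x conditions).
check_calls <- function(calls, what = "calls") {
  if (!is.matrix(calls) || is.null(rownames(calls))) {
    stopf("'%s' must be a matrix of directional calls with gene row names", what)
  }
  if (!all(calls %in% c(-1L, 0L, 1L))) stopf("'%s' contains values outside {-1, 0, +1}", what)
  invisible(calls)
}

#' UpSet-style directional intersections
#'
#' For each gene, the vector of per-condition calls; for each distinct
#' non-zero same-direction combination of conditions, the number of genes
#' showing it, up and down tallied separately.
#'
#' @param calls genes x conditions matrix of \{-1, 0, +1\} calls.
#' @return list with `membership` (the calls matrix) and `counts`, a
#'   data.frame with columns `direction`, `conditions` (comma-joined),
#'   `degree`, `n_genes`.
#' @export
directional_intersections <- function(calls) {
  check_calls(calls)
  conds <- colnames(calls) %||% paste0("cond", seq_len(ncol(calls)))
  colnames(calls) <- conds
  rows <- list()
  for (dir in c(1L, -1L)) {
    hit <- calls == dir
    keys <- apply(hit, 1L, function(h) paste(conds[h], collapse = ","))
    keys <- keys[nzchar(keys)]
    if (length(keys)) {
      tab <- table(keys)
      rows[[length(rows) + 1L]] <- data.frame(
        direction = if (dir == 1L) "up" else "down",
        conditions = names(tab),
        degree = vapply(strsplit(names(tab), ",", fixed = TRUE), length, integer(1)),
        n_genes = as.integer(tab),
        stringsAsFactors = FALSE)
    }
  }
  counts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(direction = character(), conditions = character(),
               degree = integer(), n_genes = integer(), stringsAsFactors = FALSE)
  counts <- counts[order(counts$direction, -counts$degree, -counts$n_genes), ]
  rownames(counts) <- NULL
  list(membership = calls, counts = counts)
}

#' Per-condition directional consensus
#'
#' A gene's consensus call is +1 when at least `min_conditions` conditions
#' call it up, -1 when at least `min_conditions` call it down; if both
#' directions reach the floor the majority direction wins (ties give 0).
#'
#' @param calls genes x conditions matrix of \{-1, 0, +1\}.
#' @param min_conditions minimal number of same-direction conditions.
#' @return named integer vector of consensus calls, with `n_up` / `n_down`
#'   per-gene condition counts as attributes.
#' @export
consensus_calls <- function(calls, min_conditions = 3) {
  check_calls(calls)
  n_up <- rowSums(calls == 1L)
  n_dn <- rowSums(calls == -1L)
  out <- integer(nrow(calls))
  out[n_up >= min_conditions & n_up > n_dn] <- 1L
  out[n_dn >= min_conditions & n_dn > n_up] <- -1L
  names(out) <- rownames(calls)
  attr(out, "n_up") <- n_up
  attr(out, "n_down") <- n_dn
  out
}

#' Derive the core T_FH signature
#'
#' A gene enters the core up-set iff it is called up in at least
#' `min_conditions` conditions AND up in the combined (all-conditions)
#' contrast; symmetric for down. The provenance records per-gene condition
#' counts.
#'
#' @param per_condition genes x conditions matrix of directional calls for
#'   the per-condition T_FH vs T_eff contrasts.
#' @param combined named \{-1, 0, +1\} vector for the combined contrast,
#'   over the same gene universe.
#' @param min_conditions consensus floor (default 3, i.e. >= 3 of 5
#'   infections).
#' @return a `gene_signature`.
#' @export
derive_core_signature <- function(per_condition, combined, min_conditions = 3) {
  check_calls(per_condition)
  genes <- rownames(per_condition)
  if (!setequal(genes, names(combined))) {
    stopf("combined contrast and per-condition calls use different gene universes")
  }
  combined <- combined[genes]
  cons <- consensus_calls(per_condition, min_conditions)
  up <- genes[cons == 1L & combined == 1L]
  down <- genes[cons == -1L & combined == -1L]
  counts <- data.frame(gene = genes,
                       n_conditions_up = attr(cons, "n_up"),
                       n_conditions_down = attr(cons, "n_down"),
                       combined = as.integer(combined),
                       stringsAsFactors = FALSE)
  new_gene_signature("core_tfh", up, down, provenance = list(
    rule = sprintf("same-direction call in >= %d conditions and in the combined contrast",
                   min_conditions),
    min_conditions = min_conditions,
    conditions = colnames(per_condition),
    condition_counts = counts[counts$gene %in% c(up, down), , drop = FALSE]))
}

#' Derive the T_FR signature
#'
#' The per-condition consensus is applied to the T_FR-vs-T_FH and
#' T_FR-vs-T_eff contrast families independently; a gene enters the
#' signature iff both consensus calls agree in direction.
#'
#' @param tfr_vs_tfh,tfr_vs_teff genes x conditions call matrices for the
#'   two contrast families, same gene universe.
#' @param min_conditions consensus floor per family.
#' @return a `gene_signature`.
#' @export
derive_tfr_signature <- function(tfr_vs_tfh, tfr_vs_teff, min_conditions = 3) {
  check_calls(tfr_vs_tfh, "tfr_vs_tfh")
  check_calls(tfr_vs_teff, "tfr_vs_teff")
  if (!setequal(rownames(tfr_vs_tfh), rownames(tfr_vs_teff))) {
    stopf("the two contrast families use different gene universes")
  }
  tfr_vs_teff <- tfr_vs_teff[rownames(tfr_vs_tfh), , drop = FALSE]
  c1 <- consensus_calls(tfr_vs_tfh, min_conditions)
  c2 <- consensus_calls(tfr_vs_teff, min_conditions)
  genes <- rownames(tfr_vs_tfh)
  up <- genes[c1 == 1L & c2 == 1L]
  down <- genes[c1 == -1L & c2 == -1L]
  new_gene_signature("tfr", up, down, provenance = list(
    rule = sprintf("same-direction consensus (>= %d conditions) in both T_FR contrast families",
                   min_conditions),
    min_conditions = min_conditions,
    conditions = colnames(tfr_vs_tfh)))
}

#' Derive pathogen-specific (context) signatures
#'
#' For each condition, one-vs-rest calls of the T_FH and T_eff populations
#' are combined into three components: `shared` (same-direction DE in
#' both), `tfh_unique` (DE in T_FH only), `teff_unique` (DE in T_eff only).
#' The exported per-pathogen T_FH signature is `shared` union `tfh_unique`.
#' A gene may belong to several conditions' signatures.
#'
#' @param tfh_onevrest,teff_onevrest genes x conditions call matrices of
#'   the one-vs-rest contrasts, same gene universe.
#' @return named list (one element per condition) of lists with
#'   `gene_signature` components `shared`, `tfh_unique`, `teff_unique` and
#'   `tfh_signature`.
#' @export
derive_context_signatures <- function(tfh_onevrest, teff_onevrest) {
  check_calls(tfh_onevrest, "tfh_onevrest")
  check_calls(teff_onevrest, "teff_onevrest")
  if (!setequal(rownames(tfh_onevrest), rownames(teff_onevrest))) {
    stopf("the two contrast families use different gene universes")
  }
  if (!identical(colnames(tfh_onevrest), colnames(teff_onevrest))) {
    stopf("the two contrast families cover different conditions")
  }
  teff_onevrest <- teff_onevrest[rownames(tfh_onevrest), , drop = FALSE]
  genes <- rownames(tfh_onevrest)
  out <- lapply(colnames(tfh_onevrest), function(cond) {
    a <- tfh_onevrest[, cond]
    b <- teff_onevrest[, cond]
    sig <- function(label, up_sel, down_sel) {
      new_gene_signature(paste0(cond, "_", label), genes[up_sel], genes[down_sel],
                         provenance = list(rule = label, condition = cond))
    }
    shared <- sig("shared", a == 1L & b == 1L, a == -1L & b == -1L)
    tfh_unique <- sig("tfh_unique", a == 1L & b == 0L, a == -1L & b == 0L)
    teff_unique <- sig("teff_unique", a == 0L & b == 1L, a == 0L & b == -1L)
    tfh_signature <- new_gene_signature(
      paste0(cond, "_tfh"),
      union(shared$up, tfh_unique$up), union(shared$down, tfh_unique$down),
      provenance = list(rule = "shared + tfh_unique one-vs-rest DE", condition = cond))
    list(shared = shared, tfh_unique = tfh_unique, teff_unique = teff_unique,
         tfh_signature = tfh_signature)
  })
  names(out) <- colnames(tfh_onevrest)
  out
}

#' Partition the core signature by T_FR co-expression
#'
#' Core genes fall into four groups: (1) up in T_FH, not co-expressed by
#' T_FR; (2) up in T_FH and co-expressed by T_FR (T_FR-vs-T_eff call +1);
#' (3) down in T_FH, not repressed in T_FR; (4) down in T_FH with the
#' T_FR-vs-T_eff call +1.
#'
#' @param core a `gene_signature` from [derive_core_signature()].
#' @param tfr_vs_teff_consensus named consensus call vector (e.g. from
#'   [consensus_calls()] on the T_FR-vs-T_eff family).
#' @return named integer vector mapping each core gene to its group.
#' @export
partition_core_groups <- function(core, tfr_vs_teff_consensus) {
  stopifnot(inherits(core, "gene_signature"))
  genes <- c(core$up, core$down)
  missing <- setdiff(genes, names(tfr_vs_teff_consensus))
  if (length(missing)) {
    stopf("core gene(s) missing from the T_FR-vs-T_eff calls: %s",
          paste(missing, collapse = ", "))
  }
  tfr <- tfr_vs_teff_consensus[genes]
  grp <- integer(length(genes))
  is_up <- genes %in% core$up
  grp[is_up] <- ifelse(tfr[is_up] == 1L, 2L, 1L)
  grp[!is_up] <- ifelse(tfr[!is_up] == 1L, 4L, 3L)
  stats::setNames(grp, genes)
}

#' Annotate signature genes with set memberships
#'
#' @param signature a `gene_signature`.
#' @param annotation_sets a `gene_set_collection` (e.g. cell-surface,
#'   transcriptional-regulator or Bcl-6-network sets read from GMT).
#' @return data.frame with one row per signature gene: `gene`, `direction`,
#'   one logical column per annotation set, and `novel` (TRUE when the gene
#'   is in no set).
#' @export
annotate_signature <- function(signature, annotation_sets) {
  stopifnot(inherits(signature, "gene_signature"))
  genes <- c(signature$up, signature$down)
  out <- data.frame(gene = genes,
                    direction = rep(c("up", "down"),
                                    c(length(signature$up), length(signature$down))),
                    stringsAsFactors = FALSE)
  for (nm in names(annotation_sets)) {
    out[[nm]] <- genes %in% annotation_sets[[nm]]
  }
  flag_cols <- setdiff(names(out), c("gene", "direction"))
  out$novel <- if (length(flag_cols)) {
    rowSums(as.matrix(out[flag_cols])) == 0
  } else rep(TRUE, nrow(out))
  out
}

#' Row z-score matrix for heatmaps
#'
#' Optionally averages columns within groups first, then centres and scales
#' each gene row to mean 0, sd 1 (sample-sd convention). Zero-variance rows
#' become rows of zeros with a warning.
#'
#' @param logcpm genes x samples expression matrix.
#' @param genes genes to include (must be present).
#' @param group_by optional per-sample grouping; columns are averaged per
#'   group before scaling.
#' @return z-scored matrix, rows = `genes`.
#' @export
zscore_matrix <- function(logcpm, genes = rownames(logcpm), group_by = NULL) {
  missing <- setdiff(genes, rownames(logcpm))
  if (length(missing)) stopf("gene(s) absent from the matrix: %s",
                             paste(utils::head(missing, 5L), collapse = ", "))
  m <- logcpm[genes, , drop = FALSE]
  if (!is.null(group_by)) {
    if (length(group_by) != ncol(m)) stopf("group_by length mismatch")
    groups <- unique(as.character(group_by))
    m <- vapply(groups, function(g) rowMeans(m[, group_by == g, drop = FALSE]),
                numeric(nrow(m)))
    if (nrow(logcpm[genes, , drop = FALSE]) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(genes, groups))
  }
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  degenerate <- sdv == 0 | !is.finite(sdv)
  if (any(degenerate)) {
    warnf("%d zero-variance row(s) set to zero", sum(degenerate))
    sdv[degenerate] <- 1
  }
  z <- (m - mu) / sdv
  z[degenerate, ] <- 0
  z
}

#' Derive all signatures from a fitted bulk experiment
#'
#' Convenience driver applying the core, T_FR and context rules to the
#' directional calls of a [run_bulk_de()] result.
#'
#' @param de a `tfh_de` object.
#' @param min_conditions consensus floor.
#' @return list of class `signature_set_result` with elements `core`,
#'   `tfr`, `context` (per condition), `core_groups`, and `collection`
#'   (a `gene_set_collection` ready for [write_gmt()], "_up"/"_down"
#'   suffixed).
#' @export
derive_signatures <- function(de, min_conditions = 3) {
  stopifnot(inherits(de, "tfh_de"))
  D <- de$directions
  fam <- de$families
  per_cond <- D[, fam$tfh_vs_teff, drop = FALSE]
  colnames(per_cond) <- names(fam$tfh_vs_teff)
  combined <- stats::setNames(D[, fam$tfh_vs_teff_combined], rownames(D))
  tfr_vs_tfh <- D[, fam$tfr_vs_tfh, drop = FALSE]
  colnames(tfr_vs_tfh) <- names(fam$tfr_vs_tfh)
  tfr_vs_teff <- D[, fam$tfr_vs_teff, drop = FALSE]
  colnames(tfr_vs_teff) <- names(fam$tfr_vs_teff)

  core <- derive_core_signature(per_cond, combined, min_conditions)
  tfr <- derive_tfr_signature(tfr_vs_tfh, tfr_vs_teff, min_conditions)
  tfr_cons <- consensus_calls(tfr_vs_teff, min_conditions)
  groups <- partition_core_groups(core, tfr_cons)

  context <- if (length(fam$tfh_onevrest)) {
    tfh_ovr <- D[, fam$tfh_onevrest, drop = FALSE]
    colnames(tfh_ovr) <- names(fam$tfh_onevrest)
    teff_ovr <- D[, fam$teff_onevrest, drop = FALSE]
    colnames(teff_ovr) <- names(fam$teff_onevrest)
    derive_context_signatures(tfh_ovr, teff_ovr)
  } else list()

  sigs <- c(list(core = core, tfr = tfr),
            stats::setNames(lapply(context, `[[`, "tfh_signature"), names(context)))
  collection <- signature_collection(sigs)
  structure(list(core = core, tfr = tfr, context = context,
                 core_groups = groups, collection = collection,
                 min_conditions = min_conditions),
            class = "signature_set_result")
}

#' Flatten signatures into a GMT-ready collection
#'
#' @param signatures named list of `gene_signature` objects.
#' @return a `gene_set_collection` with one "_up" (and, when present,
#'   "_down") set per signature; empty directions are skipped.
#' @export
signature_collection <- function(signatures) {
  sets <- list(); descs <- character()
  for (nm in names(signatures)) {
    sig <- signatures[[nm]]
    if (length(sig$up)) {
      sets[[paste0(nm, "_up")]] <- sig$up
      descs[paste0(nm, "_up")] <- sig$provenance$rule %||% ""
    }
    if (length(sig$down)) {
      sets[[paste0(nm, "_down")]] <- sig$down
      descs[paste0(nm, "_down")] <- sig$provenance$rule %||% ""
    }
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' @export
print.signature_set_result <- function(x, ...) {
  cat(sprintf("signature set (consensus >= %d conditions)\n", x$min_conditions))
  cat(sprintf("  core: %d up / %d down; tfr: %d up / %d down; %d context signature(s)\n",
              length(x$core$up), length(x$core$down),
              length(x$tfr$up), length(x$tfr$down), length(x$context)))
  invisible(x)
}
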