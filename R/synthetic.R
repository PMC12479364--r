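## Synthetic-data generators with known planted signature structure: a
## multi-infection sorted-population bulk experiment, a tonsil-like
## single-cell dataset with donors, planted clusters, mitochondrial genes
## and protein tags, and a spatial grid with circular germinal-centre-like
## regions. The planted truth is returned alongside every dataset and is
## the oracle for all recovery tests.

#' Simulation configuration
#'
#' Builds and validates the configuration shared by all three generators.
#' Defaults mirror the study design the package models: 5 infections x
#' 4 sorted populations x 3 replicates, negative-binomial counts with
#' dispersion 0.1, planted core/T_FR-shared/condition-specific genes at
#' |log2 FC| 1.5.
#'
#' @param n_genes number of genes.
#' @param conditions condition (infection) labels.
#' @param celltypes sorted population labels; the first two are the T_FH
#'   subsets, then T_FR, then T_eff.
#' @param replicates_per_group biological replicates per condition x
#'   celltype group.
#' @param library_size_mean,library_size_cv lognormal library-size model
#'   (reads).
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param n_core_up,n_core_down,n_tfr_shared,n_specific_per_condition
#'   planted gene counts per category.
#' @param effect_lfc planted |log2 fold change|.
#' @param baseline_log2_mean,baseline_log2_sd lognormal model of baseline
#'   gene abundance (log2 scale).
#' @param min_planted_expression planted genes are drawn only from genes
#'   whose expected baseline count at the mean library size is at least
#'   this, so recovery measures the rule rather than the expression filter.
#' @param force_small_library force the first sample's library below 1
#'   million reads to exercise the library-size filter.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial
#'   ("mt-" prefix) in single-cell data.
#' @param mito_baseline,mito_high_level,mito_high_fraction expected
#'   mitochondrial count fraction of ordinary cells, of damaged cells, and
#'   the fraction of damaged cells.
#' @param n_clusters,n_cells_per_cluster,n_donors,n_markers_per_cluster,
#'   cell_library_mean,cell_library_cv single-cell structure.
#' @param n_proteins protein tags (one elevated per cluster, cycling).
#' @param grid_size,n_regions,region_radius,n_spots spatial structure.
#' @param seed master seed; each generator derives its own stream.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       conditions = c("lcmv", "influenza", "tmuris",
                                      "hpolygyrus", "crodentium"),
                       celltypes = c("tfh_il21pos", "tfh_il21neg", "tfr", "teff"),
                       replicates_per_group = 3,
                       library_size_mean = 2e6, library_size_cv = 0.3,
                       dispersion = 0.1,
                       n_core_up = 200, n_core_down = 200, n_tfr_shared = 100,
                       n_specific_per_condition = 100,
                       effect_lfc = 1.5,
                       baseline_log2_mean = 4, baseline_log2_sd = 2,
                       min_planted_expression = 50,
                       force_small_library = FALSE,
                       mito_gene_fraction = 0.05,
                       mito_baseline = 0.05, mito_high_level = 0.30,
                       mito_high_fraction = 0.05,
                       n_clusters = 3, n_cells_per_cluster = 200, n_donors = 4,
                       n_markers_per_cluster = 100,
                       cell_library_mean = 2000, cell_library_cv = 0.3,
                       n_proteins = 10,
                       grid_size = 100, n_regions = 3, region_radius = 10,
                       n_spots = 1000,
                       seed = 1) {
  cfg <- as.list(environment())
  count_fields <- c("n_genes", "replicates_per_group", "n_core_up", "n_core_down",
                    "n_tfr_shared", "n_specific_per_condition", "n_clusters",
                    "n_cells_per_cluster", "n_donors", "n_markers_per_cluster",
                    "n_proteins", "n_regions", "n_spots")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v)) {
      stopf("config field '%s' must be a non-negative integer (got %s)", f, format(v))
    }
  }
  if (cfg$dispersion < 0) stopf("config field 'dispersion' must be >= 0")
  if (!is.finite(cfg$effect_lfc)) stopf("config field 'effect_lfc' must be finite")
  if (cfg$library_size_mean <= 0) stopf("config field 'library_size_mean' must be positive")
  if (cfg$mito_gene_fraction < 0 || cfg$mito_gene_fraction > 1) {
    stopf("config field 'mito_gene_fraction' must lie in [0, 1]")
  }
  planted <- cfg$n_core_up + cfg$n_core_down + cfg$n_tfr_shared +
    cfg$n_specific_per_condition * length(cfg$conditions)
  if (planted > cfg$n_genes) {
    stopf("planted gene counts sum to %d but n_genes is only %d", planted, cfg$n_genes)
  }
  if (length(cfg$celltypes) < 4L) stopf("config field 'celltypes' needs the four sorted populations")
  structure(cfg, class = "sim_config")
}

## Baseline relative abundances and the planted category assignment shared
## by the generators.
.plant_genes <- function(cfg) {
  G <- cfg$n_genes
  genes <- sprintf("gene%05d", seq_len(G))
  x <- 2^stats::rnorm(G, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  q <- x / sum(x)
  eligible <- which(q * cfg$library_size_mean >= cfg$min_planted_expression)
  need <- cfg$n_core_up + cfg$n_core_down + cfg$n_tfr_shared +
    cfg$n_specific_per_condition * length(cfg$conditions)
  if (length(eligible) < need) {
    stopf("only %d gene(s) pass the planted-expression floor but %d are needed",
          length(eligible), need)
  }
  chosen <- sample(eligible, need)
  category <- rep("null", G)
  pos <- 0L
  take <- function(n) {
    out <- chosen[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  category[take(cfg$n_core_up)] <- "core_up"
  category[take(cfg$n_core_down)] <- "core_down"
  category[take(cfg$n_tfr_shared)] <- "tfr_shared"
  for (cond in cfg$conditions) {
    category[take(cfg$n_specific_per_condition)] <- paste0("specific:", cond)
  }
  list(genes = genes, q = q, category = category)
}

#' Generate a multi-condition bulk RNA-seq experiment
#'
#' Counts are NB(mu, phi) around an analytic mean model: per-gene baseline
#' abundance times library size times 2^(planted effect). Core genes are
#' shifted in the T_FH subsets (vs T_eff) in every condition; T_FR-shared
#' genes in both T_FH and T_FR; condition-specific genes in the T_FH of
#' their condition only.
#'
#' @param config a [sim_config()].
#' @return list of class `bulk_sim` with `counts` (genes x samples),
#'   `samples` (condition, celltype, replicate), `truth` (per-gene category,
#'   planted lfc, seed), `mu` (the analytic mean matrix) and `config`.
#' @export
simulate_bulk <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    pg <- .plant_genes(config)
    tfh <- config$celltypes[1:2]
    tfr <- config$celltypes[3L]
    samples <- expand.grid(replicate = seq_len(config$replicates_per_group),
                           celltype = config$celltypes,
                           condition = config$conditions,
                           stringsAsFactors = FALSE)
    samples <- samples[, c("condition", "celltype", "replicate")]
    rownames(samples) <- with(samples, paste(condition, celltype, replicate, sep = "."))
    S <- nrow(samples)
    G <- config$n_genes
    ## planted log2 effect per gene x sample
    delta <- matrix(0, G, S, dimnames = list(pg$genes, rownames(samples)))
    in_tfh <- samples$celltype %in% tfh
    in_tfr <- samples$celltype == tfr
    delta[pg$category == "core_up", in_tfh] <- config$effect_lfc
    delta[pg$category == "core_down", in_tfh] <- -config$effect_lfc
    delta[pg$category == "tfr_shared", in_tfh | in_tfr] <- config$effect_lfc
    for (cond in config$conditions) {
      sel <- in_tfh & samples$condition == cond
      delta[pg$category == paste0("specific:", cond), sel] <- config$effect_lfc
    }
    cv <- config$library_size_cv
    sdlog <- sqrt(log(1 + cv^2))
    libs <- stats::rlnorm(S, log(config$library_size_mean) - sdlog^2 / 2, sdlog)
    if (config$force_small_library) libs[1L] <- 5e5
    mu <- (pg$q * 2^delta) %*% diag(libs)
    dimnames(mu) <- dimnames(delta)
    counts <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(G * S, mu = mu, size = 1 / config$dispersion), G, S)
    } else {
      matrix(stats::rpois(G * S, lambda = mu), G, S)
    }
    dimnames(counts) <- dimnames(delta)
    storage.mode(counts) <- "integer"
    truth <- list(category = stats::setNames(pg$category, pg$genes),
                  effect_lfc = config$effect_lfc,
                  baseline_proportion = stats::setNames(pg$q, pg$genes),
                  seed = config$seed)
    structure(list(counts = counts, samples = samples, truth = truth,
                   mu = mu, library_sizes = stats::setNames(libs, rownames(samples)),
                   config = config), class = "bulk_sim")
  })
}

#' Analytic expectation of the signature rules on a simulated truth
#'
#' Returns the gene sets that the derivation rules *should* recover given
#' the planted mean model: T_FR-shared genes are shifted in T_FH vs T_eff
#' in every condition and therefore legitimately satisfy the core rule, so
#' they belong to the expected core up-set; the planted T_FR-shared genes
#' are not differential between T_FR and T_FH and so the expected T_FR
#' signature is empty under the default design.
#'
#' @param truth the `truth` element of a [simulate_bulk()] result.
#' @return list with `core_up`, `core_down`, `context` (per-condition
#'   expected up-genes), `tfr_up`, `tfr_down`.
#' @export
expected_signatures <- function(truth) {
  cat_ <- truth$category
  genes <- names(cat_)
  conds <- sub("^specific:", "", grep("^specific:", cat_, value = TRUE))
  context <- lapply(unique(conds), function(cond) {
    genes[cat_ == paste0("specific:", cond)]
  })
  names(context) <- unique(conds)
  list(core_up = genes[cat_ %in% c("core_up", "tfr_shared")],
       core_down = genes[cat_ == "core_down"],
       context = context,
       tfr_up = character(), tfr_down = character())
}

## Cluster expression profiles for the single-cell / spatial generators:
## baseline proportions with marker blocks elevated, mitochondrial mass
## pinned to `mito_level`, renormalized to 1.
.cluster_profile <- function(q, markers, effect_lfc, mito_idx, mito_level) {
  p <- q
  p[markers] <- p[markers] * 2^effect_lfc
  if (length(mito_idx)) {
    p_non <- p
    p_non[mito_idx] <- 0
    p_non <- p_non / sum(p_non) * (1 - mito_level)
    p_non[mito_idx] <- mito_level / length(mito_idx)
    p <- p_non
  } else {
    p <- p / sum(p)
  }
  p
}

#' Generate a tonsil-like single-cell experiment
#'
#' Cells are drawn per planted cluster (Poisson counts around per-cell
#' scaled cluster profiles) with donor labels, mitochondrial genes flagged
#' by the "mt-" prefix, a configurable fraction of damaged high-mito cells,
#' and protein-tag counts with one elevated tag per cluster.
#'
#' @param config a [sim_config()].
#' @return list of class `sc_sim` with `cells` (cells x genes), `cell_meta`
#'   (donor, cluster, mito_high), `proteins` (cells x tags), `truth`
#'   (marker genes per cluster, damaged cells, seed) and `config`.
#' @export
simulate_singlecell <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 2L), {
    G <- config$n_genes
    n_mito <- round(config$mito_gene_fraction * G)
    genes <- sprintf("gene%05d", seq_len(G))
    if (n_mito > 0) genes[seq_len(n_mito)] <- sprintf("mt-gene%03d", seq_len(n_mito))
    mito_idx <- seq_len(n_mito)
    x <- 2^stats::rnorm(G, config$baseline_log2_mean, config$baseline_log2_sd)
    q <- x / sum(x)
    ## disjoint marker blocks per cluster, drawn from expressed genes
    eligible <- setdiff(order(q, decreasing = TRUE)[seq_len(min(G, 2000L))], mito_idx)
    need <- config$n_clusters * config$n_markers_per_cluster
    if (length(eligible) < need) stopf("not enough genes for %d marker blocks", config$n_clusters)
    picked <- sample(eligible, need)
    markers <- split(picked, rep(seq_len(config$n_clusters),
                                 each = config$n_markers_per_cluster))
    profiles <- lapply(seq_len(config$n_clusters), function(cl) {
      .cluster_profile(q, markers[[cl]], config$effect_lfc, mito_idx,
                       config$mito_baseline)
    })
    profiles_high <- lapply(seq_len(config$n_clusters), function(cl) {
      .cluster_profile(q, markers[[cl]], config$effect_lfc, mito_idx,
                       config$mito_high_level)
    })
    n_cells <- config$n_clusters * config$n_cells_per_cluster
    cluster <- rep(seq_len(config$n_clusters), each = config$n_cells_per_cluster)
    donor <- sample(paste0("donor", seq_len(config$n_donors)), n_cells, replace = TRUE)
    mito_high <- stats::runif(n_cells) < config$mito_high_fraction
    cv <- config$cell_library_cv
    sdlog <- sqrt(log(1 + cv^2))
    libs <- stats::rlnorm(n_cells, log(config$cell_library_mean) - sdlog^2 / 2, sdlog)
    cells <- matrix(0L, n_cells, G,
                    dimnames = list(sprintf("cell%04d", seq_len(n_cells)), genes))
    for (i in seq_len(n_cells)) {
      p <- if (mito_high[i]) profiles_high[[cluster[i]]] else profiles[[cluster[i]]]
      cells[i, ] <- stats::rpois(G, libs[i] * p)
    }
    proteins <- NULL
    if (config$n_proteins > 0) {
      tag_base <- 20
      proteins <- matrix(0L, n_cells, config$n_proteins,
                         dimnames = list(rownames(cells),
                                         sprintf("tag%02d", seq_len(config$n_proteins))))
      elevated_tag <- ((seq_len(config$n_clusters) - 1L) %% config$n_proteins) + 1L
      for (i in seq_len(n_cells)) {
        mu <- rep(tag_base, config$n_proteins)
        mu[elevated_tag[cluster[i]]] <- tag_base * 5
        proteins[i, ] <- stats::rpois(config$n_proteins, mu)
      }
    }
    cell_meta <- data.frame(donor = donor, cluster = cluster,
                            mito_high = mito_high,
                            row.names = rownames(cells),
                            stringsAsFactors = FALSE)
    truth <- list(markers = lapply(markers, function(ix) genes[ix]),
                  mito_genes = genes[mito_idx],
                  mito_high_cells = rownames(cells)[mito_high],
                  seed = config$seed)
    structure(list(cells = cells, cell_meta = cell_meta, proteins = proteins,
                   truth = truth, config = config), class = "sc_sim")
  })
}

#' Generate a spatial experiment with germinal-centre-like regions
#'
#' Cells (Xenium-like: spots = cells) are placed uniformly on a
#' `grid_size` x `grid_size` plane; `n_regions` circular regions are
#' planted, and cells falling inside a region are drawn from a
#' signature-positive profile (a planted up-gene block elevated by
#' `effect_lfc`), cells outside from background.
#'
#' @param config a [sim_config()].
#' @param mode `"xenium"` (cell-level, default) or `"visium"` (cells
#'   aggregated into square bins; bin labels inherit the majority region).
#' @param bin_size bin edge for visium mode (default `grid_size / 20`).
#' @return list of class `spatial_sim` with `counts` (spots x genes),
#'   `coords` (x, y), `region` (region label per spot, NA outside),
#'   `truth` (signature genes, region centres, seed) and `config`.
#' @export
simulate_spatial <- function(config = sim_config(), mode = c("xenium", "visium"),
                             bin_size = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (config$n_regions > 0 && 2 * config$region_radius > config$grid_size) {
    stopf("region_radius %g does not fit in a grid of size %g",
          config$region_radius, config$grid_size)
  }
  with_seed(child_seed(config$seed, 3L), {
    G <- config$n_genes
    genes <- sprintf("gene%05d", seq_len(G))
    x <- 2^stats::rnorm(G, config$baseline_log2_mean, config$baseline_log2_sd)
    q <- x / sum(x)
    sig <- sample(order(q, decreasing = TRUE)[seq_len(min(G, 2000L))],
                  min(config$n_markers_per_cluster, G))
    p_bg <- q / sum(q)
    p_sig <- q
    p_sig[sig] <- p_sig[sig] * 2^config$effect_lfc
    p_sig <- p_sig / sum(p_sig)
    n <- config$n_spots
    coords <- data.frame(x = stats::runif(n, 0, config$grid_size),
                         y = stats::runif(n, 0, config$grid_size))
    rownames(coords) <- sprintf("spot%04d", seq_len(n))
    region <- rep(NA_character_, n)
    centres <- NULL
    if (config$n_regions > 0) {
      r <- config$region_radius
      centres <- data.frame(
        x = stats::runif(config$n_regions, r, config$grid_size - r),
        y = stats::runif(config$n_regions, r, config$grid_size - r),
        row.names = paste0("region", seq_len(config$n_regions)))
      for (k in seq_len(config$n_regions)) {
        inside <- (coords$x - centres$x[k])^2 + (coords$y - centres$y[k])^2 <= r^2
        region[inside & is.na(region)] <- rownames(centres)[k]
      }
    }
    cv <- config$cell_library_cv
    sdlog <- sqrt(log(1 + cv^2))
    libs <- stats::rlnorm(n, log(config$cell_library_mean) - sdlog^2 / 2, sdlog)
    counts <- matrix(0L, n, G, dimnames = list(rownames(coords), genes))
    for (i in seq_len(n)) {
      p <- if (is.na(region[i])) p_bg else p_sig
      counts[i, ] <- stats::rpois(G, libs[i] * p)
    }
    truth <- list(signature_genes = genes[sig], centres = centres,
                  seed = config$seed)
    out <- list(counts = counts, coords = coords, region = region,
                truth = truth, config = config)
    if (mode == "visium") {
      bin_size <- bin_size %||% (config$grid_size / 20)
      bx <- floor(coords$x / bin_size); by <- floor(coords$y / bin_size)
      key <- paste0("bin_", bx, "_", by)
      agg <- pseudobulk(counts, key, min_cells = 1)
      bin_region <- vapply(colnames(agg$counts), function(b) {
        r <- region[key == b]
        r <- r[!is.na(r)]
        if (length(r)) names(sort(table(r), decreasing = TRUE))[1L] else NA_character_
      }, character(1))
      bin_coords <- data.frame(
        x = vapply(colnames(agg$counts), function(b) mean(coords$x[key == b]), numeric(1)),
        y = vapply(colnames(agg$counts), function(b) mean(coords$y[key == b]), numeric(1)),
        row.names = colnames(agg$counts))
      out$counts <- t(agg$counts)
      out$coords <- bin_coords
      out$region <- unname(bin_region)
    }
    structure(out, class = "spatial_sim")
  })
}
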