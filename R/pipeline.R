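## End-to-end orchestration: a single YAML-able configuration drives
## simulate -> derive-signatures -> project, each output accompanied by a
## provenance record (config digest, seeds, package version). A thin
## Rscript wrapper over run_pipeline() ships in inst/scripts/fhsig.R.

#' Default pipeline configuration
#'
#' One flat list of stage parameters mirroring the package defaults:
#' TREAT fold-change floor 1.1, FDR 0.05, consensus over >= 3 conditions,
#' 1-million-read library floor, 10-cell pseudobulk floor, up-only
#' projection scoring. Unknown keys in an override list are rejected.
#'
#' @param overrides named list (e.g. from [yaml::read_yaml()]) of values to
#'   replace.
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1,
    n_genes = 5000,
    replicates_per_group = 3,
    n_core_up = 200,
    n_core_down = 200,
    n_tfr_shared = 100,
    n_specific_per_condition = 100,
    effect_lfc = 1.5,
    dispersion = 0.1,
    fc_threshold = 1.1,
    fdr = 0.05,
    min_conditions = 3,
    min_reads = 1e6,
    min_cells = 10,
    score_use = "up_only"
  )
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Run the simulate / derive-signatures / project pipeline
#'
#' Generates a synthetic bulk experiment, derives the core, T_FR and
#' pathogen-specific signatures, scores the T_FH samples against the
#' context signatures, and writes counts, metadata, truth, signatures
#' (GMT), scores and a provenance record to `out_dir`. Re-running with the
#' same configuration reproduces every numeric output byte for byte.
#'
#' @param config a [pipeline_config()] (or override list, or path to a
#'   YAML file).
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the configured one.
#' @return invisibly, a list with the simulation, the DE fit, the
#'   signature set and the score matrix.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- simulate_bulk(sim_config(
    n_genes = config$n_genes,
    replicates_per_group = config$replicates_per_group,
    n_core_up = config$n_core_up,
    n_core_down = config$n_core_down,
    n_tfr_shared = config$n_tfr_shared,
    n_specific_per_condition = config$n_specific_per_condition,
    effect_lfc = config$effect_lfc,
    dispersion = config$dispersion,
    seed = config$seed))
  write_counts(sim$counts, file.path(out_dir, "counts.tsv"))
  write_metadata(sim$samples, file.path(out_dir, "samples.tsv"))
  utils::write.table(
    data.frame(gene = names(sim$truth$category), category = sim$truth$category),
    file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  de <- run_bulk_de(sim$counts, sim$samples,
                    fc_threshold = config$fc_threshold, fdr = config$fdr,
                    min_reads = config$min_reads)
  sigs <- derive_signatures(de, min_conditions = config$min_conditions)
  write_gmt(sigs$collection, file.path(out_dir, "signatures.gmt"))

  tfh_cols <- rownames(de$samples)[de$samples$celltype %in% c("tfh_il21pos", "tfh_il21neg")]
  context_sigs <- lapply(sigs$context, `[[`, "tfh_signature")
  scores <- score_matrix(de$logcpm[, tfh_cols, drop = FALSE], context_sigs,
                         use = config$score_use)
  utils::write.table(
    data.frame(sample = rownames(scores), scores, check.names = FALSE),
    file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  provenance <- list(
    package = "tfhsig",
    version = as.character(utils::packageVersion("tfhsig")),
    seed = config$seed,
    config = unclass(config),
    outputs = c("counts.tsv", "samples.tsv", "truth.tsv", "signatures.gmt",
                "scores.tsv"))
  yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
  invisible(list(sim = sim, de = de, signatures = sigs, scores = scores))
}
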