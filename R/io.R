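## I/O for the standard formats the pipeline touches: TSV/CSV count matrices,
## MatrixMarket MTX with row/column-name sidecars, GMT gene-set collections,
## sample metadata tables, and dataset validation.

#' Read a count matrix from TSV/CSV or MatrixMarket format
#'
#' The canonical orientation is genes x samples for bulk data and
#' cells x genes for single-cell data; the orientation is recorded, never
#' inferred. TSV/CSV files must carry a header row and identifiers in the
#' first column. MTX files require two sidecar files holding the row and
#' column names, one identifier per line, located at `<path>.rownames` and
#' `<path>.colnames` (or passed explicitly).
#'
#' @param path file to read.
#' @param format `"tsv"`, `"csv"` or `"mtx"`. Default guesses from the
#'   file extension.
#' @param orientation `"genes_by_samples"` or `"cells_by_genes"`; stored as
#'   an attribute on the returned matrix.
#' @param rownames_path,colnames_path sidecar paths for MTX input.
#' @return integer matrix with `dimnames` and an `orientation` attribute.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        orientation = c("genes_by_samples", "cells_by_genes"),
                        rownames_path = NULL, colnames_path = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stopf("cannot guess format from extension '%s'", ext))
  }
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids)) {
      stopf("duplicate identifier(s) in %s: %s", path,
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stopf("non-numeric entries in %s", path)
    rownames(m) <- ids
  } else {
    rn_path <- rownames_path %||% paste0(path, ".rownames")
    cn_path <- colnames_path %||% paste0(path, ".colnames")
    for (p in c(rn_path, cn_path)) {
      if (!file.exists(p)) stopf("MTX sidecar file not found: %s", p)
    }
    mm <- Matrix::readMM(path)
    rn <- readLines(rn_path)
    cn <- readLines(cn_path)
    if (nrow(mm) != length(rn) || ncol(mm) != length(cn)) {
      stopf("MTX dimensions %dx%d do not match sidecars (%d rownames, %d colnames)",
            nrow(mm), ncol(mm), length(rn), length(cn))
    }
    m <- as.matrix(mm)
    dimnames(m) <- list(rn, cn)
  }
  check_count_matrix(m, what = path)
  storage.mode(m) <- "integer"
  attr(m, "orientation") <- orientation
  m
}

#' Write a count matrix to TSV or MatrixMarket format
#'
#' @param counts named integer matrix.
#' @param path output file. For MTX, sidecar files `<path>.rownames` and
#'   `<path>.colnames` are written alongside.
#' @param format `"tsv"` or `"mtx"`.
#' @param id_column header of the identifier column for TSV output.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx"),
                         id_column = "gene_id") {
  format <- match.arg(format)
  check_count_matrix(counts, what = "counts")
  if (format == "tsv") {
    df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_column
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Read / write a sample or cell metadata table
#'
#' Plain TSV with a header; the first column holds the sample/cell
#' identifiers and becomes the row names.
#'
#' @param path file path.
#' @return data.frame with identifier row names.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stopf("duplicate identifier(s) in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- df[, -1L, drop = FALSE]
  rownames(out) <- ids
  out
}

#' @rdname read_metadata
#' @param meta data.frame with identifier row names.
#' @param id_column header used for the identifier column.
#' @export
write_metadata <- function(meta, path, id_column = "sample_id") {
  df <- data.frame(id = rownames(meta), meta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT dialect: one set per line, `name <TAB> description <TAB> member...`.
#' Set order is preserved and the round trip through [write_gmt()] is
#' lossless.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stopf("GMT line %d has %d field(s); need name, description and >=1 member",
            i, length(f))
    }
    nms[i] <- f[1L]
    descs[i] <- f[2L]
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) stopf("GMT line %d ('%s') has no members", i, f[1L])
    sets[[i]] <- members
  }
  if (anyDuplicated(nms)) {
    stopf("duplicate gene-set name(s): %s",
          paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  structure(sets, descriptions = stats::setNames(descs, nms),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @export
write_gmt <- function(collection, path) {
  if (length(collection) == 0L) stopf("empty gene-set collection")
  if (is.null(names(collection)) || any(!nzchar(names(collection)))) {
    stopf("all gene sets must be named")
  }
  descs <- attr(collection, "descriptions") %||%
    stats::setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    members <- collection[[nm]]
    if (length(members) == 0L) stopf("gene set '%s' has no members", nm)
    paste(c(nm, descs[[nm]] %||% "", members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a count matrix against its metadata table
#'
#' Produces a report rather than stopping: each finding has a severity
#' (`"fatal"` or `"warning"`) and a message. Pipelines refuse to proceed on
#' fatal findings via [assert_valid_dataset()].
#'
#' @param counts genes x samples (or cells x genes) count matrix.
#' @param meta metadata data.frame keyed by row names.
#' @param sample_dim which matrix dimension holds the units described by
#'   `meta` (2 = columns, the bulk convention; 1 = rows).
#' @param required_factors metadata columns that must be present.
#' @return data.frame with columns `severity` and `message`; zero rows when
#'   the dataset is clean.
#' @export
validate_dataset <- function(counts, meta, sample_dim = 2L,
                             required_factors = character()) {
  findings <- list()
  add <- function(severity, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, message = msg, stringsAsFactors = FALSE)
  }
  ids <- dimnames(counts)[[sample_dim]]
  missing_meta <- setdiff(ids, rownames(meta))
  if (length(missing_meta)) {
    add("fatal", sprintf("sample(s) absent from metadata: %s",
                         paste(missing_meta, collapse = ", ")))
  }
  extra_meta <- setdiff(rownames(meta), ids)
  if (length(extra_meta)) {
    add("warning", sprintf("metadata row(s) with no matching sample: %s",
                           paste(extra_meta, collapse = ", ")))
  }
  for (f in required_factors) {
    if (!f %in% names(meta)) add("fatal", sprintf("missing factor column '%s'", f))
  }
  totals <- if (sample_dim == 2L) colSums(counts) else rowSums(counts)
  zero <- ids[totals == 0]
  if (length(zero)) {
    add("warning", sprintf("all-zero sample(s): %s", paste(zero, collapse = ", ")))
  }
  if (any(counts < 0)) add("fatal", "negative count values present")
  if (length(findings) == 0L) {
    return(data.frame(severity = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' @rdname validate_dataset
#' @export
assert_valid_dataset <- function(counts, meta, sample_dim = 2L,
                                 required_factors = character()) {
  rep <- validate_dataset(counts, meta, sample_dim, required_factors)
  fatal <- rep$message[rep$severity == "fatal"]
  if (length(fatal)) {
    stopf("dataset validation failed:\n%s", paste("-", fatal, collapse = "\n"))
  }
  invisible(rep)
}
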