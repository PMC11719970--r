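# Reading/writing beta matrices, labels, ages and CpG->gene manifests, plus
# the cross-platform probe intersection and the gene-set CpG filter.
#
# The canonical in-memory form of a beta matrix is a plain numeric matrix,
# samples in rows, CpG probes in columns, with sample ids as rownames and
# probe ids as colnames. GEO series-matrix style files are probe-major, so
# file orientation is always an explicit flag, never guessed.

#' Construct and validate a beta-value matrix
#'
#' @param values Numeric matrix of methylation fractions in `[0, 1]`,
#'   samples x probes.
#' @param sample_ids,cpg_ids Optional identifier vectors; taken from the
#'   dimnames of `values` when omitted.
#' @return The validated matrix with dimnames set.
#' @export
beta_matrix <- function(values, sample_ids = rownames(values),
                        cpg_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stopf("beta matrix must have at least one sample and one probe")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(cpg_ids)) cpg_ids <- sprintf("cg%08d", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stopf("duplicate sample identifiers")
  if (anyDuplicated(cpg_ids)) stopf("duplicate probe identifiers")
  if (length(sample_ids) != nrow(values) || length(cpg_ids) != ncol(values)) {
    stopf("identifier lengths do not match matrix dimensions")
  }
  if (anyNA(values)) stopf("beta matrix contains missing values")
  if (min(values) < 0 || max(values) > 1) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1L, ]
    stopf("beta value %.6g outside [0, 1] at sample '%s', probe '%s'",
          values[bad[1L], bad[2L]], sample_ids[bad[1L]], cpg_ids[bad[2L]])
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(cpg_ids))
  values
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a beta-value matrix from delimited text
#'
#' Expects one header row and one identifier column. Probe-major files
#' (GEO series-matrix style) are transposed to the canonical samples x probes
#' orientation.
#'
#' @param path File path (`.csv` implies comma, anything else tab; override
#'   with `delim`).
#' @param orientation `"samples_as_rows"` or `"probes_as_rows"`.
#' @param delim Optional field delimiter.
#' @param missing `"strict"` rejects missing values; `"lenient"` mean-imputes
#'   them per probe and emits a message.
#' @return Validated numeric matrix, samples x probes.
#' @export
read_beta_matrix <- function(path,
                             orientation = c("samples_as_rows",
                                             "probes_as_rows"),
                             delim = NULL,
                             missing = c("strict", "lenient")) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  dt <- data.table::fread(path, sep = infer_delim(path, delim),
                          header = TRUE, colClasses = "character",
                          data.table = FALSE, fill = FALSE)
  if (ncol(dt) < 2L) stopf("'%s': expected an id column plus data columns", path)
  ids <- dt[[1L]]
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "" & toupper(vals) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("'%s': non-numeric value '%s' at row '%s', column '%s'", path,
          vals[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
          colnames(vals)[bad[1L, 2L]])
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (orientation == "probes_as_rows") num <- t(num)
  if (anyNA(num)) {
    if (missing == "strict") {
      stopf("'%s': missing values present (use missing = \"lenient\" to mean-impute per probe)",
            path)
    }
    n_imp <- sum(is.na(num))
    for (j in seq_len(ncol(num))) {
      nas <- is.na(num[, j])
      if (any(nas)) {
        if (all(nas)) stopf("probe '%s' has no observed values", colnames(num)[j])
        num[nas, j] <- mean(num[!nas, j])
      }
    }
    message(sprintf("mean-imputed %d missing beta values per probe", n_imp))
  }
  beta_matrix(num)
}

#' Write a beta-value matrix to delimited text
#'
#' Values are rounded to `digits` decimals; a read of the written file
#' round-trips within `10^-digits`. Output is locale-independent (dot decimal
#' separator).
#'
#' @param beta Validated beta matrix (samples x probes).
#' @param path Output path; `.csv` implies comma, anything else tab.
#' @param orientation Orientation of the written file.
#' @param delim Optional field delimiter.
#' @param digits Decimal precision (default 6).
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(beta, path,
                              orientation = c("samples_as_rows",
                                              "probes_as_rows"),
                              delim = NULL, digits = 6L) {
  orientation <- match.arg(orientation)
  beta <- beta_matrix(beta)
  m <- round(beta, digits)
  if (orientation == "probes_as_rows") {
    out <- data.table::data.table(cpg_id = colnames(m))
    out <- cbind(out, data.table::as.data.table(t(m)))
  } else {
    out <- data.table::data.table(sample_id = rownames(m))
    out <- cbind(out, data.table::as.data.table(m))
  }
  data.table::fwrite(out, path, sep = infer_delim(path, delim))
  invisible(path)
}

#' Read sample labels
#'
#' Two-column delimited file (`sample_id`, `label`). Labels may be binary
#' (`0`/`1`), class names, or one-hot strings (`1000`, `0100`, `0010`,
#' `0001`), which are decoded to class names.
#'
#' @param path File path.
#' @param delim Optional field delimiter.
#' @return Named character vector of labels (names are sample ids).
#' @export
read_labels <- function(path, delim = NULL) {
  dt <- data.table::fread(path, sep = infer_delim(path, delim), header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) != 2L) stopf("'%s': expected two columns (sample_id, label)", path)
  if (anyDuplicated(dt[[1L]])) stopf("'%s': duplicate sample ids", path)
  labels <- dt[[2L]]
  if (all(labels %in% onehot_codes())) labels <- decode_onehot(labels)
  structure(labels, names = dt[[1L]])
}

#' Write sample labels
#' @param labels Named vector of labels (names are sample ids).
#' @param path Output path.
#' @param delim Optional field delimiter.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path, delim = NULL) {
  data.table::fwrite(
    data.table::data.table(sample_id = names(labels),
                           label = as.character(labels)),
    path, sep = infer_delim(path, delim))
  invisible(path)
}

#' Decode one-hot class strings to class labels
#'
#' `1000` = neurodegenerative, `0100` = bone-degenerative, `0010` = breast
#' cancer, `0001` = healthy. Each string must activate exactly one class.
#'
#' @param codes Character vector of one-hot strings.
#' @return Character vector of class labels.
#' @export
decode_onehot <- function(codes) {
  codes <- as.character(codes)
  map <- onehot_codes()
  bad <- setdiff(unique(codes), map)
  if (length(bad) > 0L) stopf("invalid one-hot code '%s'", bad[1L])
  names(map)[match(codes, map)]
}

#' Encode class labels as one-hot strings
#' @param labels Character vector of the four canonical class labels.
#' @return Character vector of one-hot strings.
#' @export
encode_onehot <- function(labels) {
  map <- onehot_codes()
  bad <- setdiff(unique(as.character(labels)), names(map))
  if (length(bad) > 0L) stopf("unknown class label '%s'", bad[1L])
  unname(map[as.character(labels)])
}

#' Read per-sample ages
#' @param path Two-column file (`sample_id`, `age_years`).
#' @param delim Optional field delimiter.
#' @return Named numeric vector of ages in years.
#' @export
read_ages <- function(path, delim = NULL) {
  dt <- data.table::fread(path, sep = infer_delim(path, delim), header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) != 2L) stopf("'%s': expected two columns (sample_id, age_years)", path)
  structure(as.numeric(dt[[2L]]), names = as.character(dt[[1L]]))
}

#' Read a CpG-to-gene manifest
#'
#' Two-column file (`cpg_id`, `gene_symbol`); many-to-many rows allowed.
#'
#' @param path File path.
#' @param delim Optional field delimiter.
#' @return data.frame with columns `cpg_id` and `gene_symbol`.
#' @export
read_gene_manifest <- function(path, delim = NULL) {
  dt <- data.table::fread(path, sep = infer_delim(path, delim), header = TRUE,
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) != 2L) stopf("'%s': expected two columns (cpg_id, gene_symbol)", path)
  names(dt) <- c("cpg_id", "gene_symbol")
  if (any(dt$cpg_id == "") || any(dt$gene_symbol == "")) {
    stopf("'%s': empty identifiers in manifest", path)
  }
  dt
}

#' Intersect probe sets across platforms
#'
#' Emulates taking the CpG probes shared by 27K/450K/EPIC-style matrices
#' before any downstream analysis.
#'
#' @param matrices List of two or more beta matrices.
#' @return Sorted character vector of shared probe ids.
#' @export
intersect_probes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L) {
    stopf("need a list of at least two beta matrices")
  }
  common <- Reduce(intersect, lapply(matrices, colnames))
  if (length(common) == 0L) stopf("probe sets have an empty intersection")
  sort(common)
}

#' Subset and column-align matrices to a shared probe set
#'
#' Convenience wrapper around [intersect_probes()]: every matrix is reduced
#' to the shared probes, in the same (sorted) column order.
#'
#' @param matrices List of beta matrices.
#' @param probes Optional probe ids to align to; defaults to the intersection.
#' @return List of aligned matrices.
#' @export
align_to_probes <- function(matrices, probes = NULL) {
  if (is.null(probes)) probes <- intersect_probes(matrices)
  lapply(matrices, function(m) {
    miss <- setdiff(probes, colnames(m))
    if (length(miss) > 0L) stopf("probe '%s' absent from a matrix", miss[1L])
    m[, probes, drop = FALSE]
  })
}

#' Filter CpGs to those mapping to a gene list
#'
#' Keeps, in input order, the CpGs whose manifest gene set intersects
#' `genes` (the step that reduces a top-ranked CpG list to the subset backed
#' by a curated gene list).
#'
#' @param cpgs Character vector of CpG ids (order preserved).
#' @param genes Character vector of gene symbols.
#' @param manifest data.frame from [read_gene_manifest()].
#' @return Character vector, subset of `cpgs`.
#' @export
filter_cpgs_by_genes <- function(cpgs, genes, manifest) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) {
    stopf("manifest must be a nonempty data.frame")
  }
  hits <- unique(manifest$cpg_id[manifest$gene_symbol %in% genes])
  cpgs[cpgs %in% hits]
}
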