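#' Multi-tissue, multi-age expression dataset
#'
#' Container for a genes-by-samples expression matrix together with per-sample
#' annotations and, optionally, a parallel matrix of MAS5-style
#' Present/Absent/Marginal detection calls. Values are kept exactly as
#' supplied; the `scale` flag travels with the dataset and is interpreted by
#' the fold-change rule, never applied by the container itself. Missing
#' measurements are represented by `NA` (an explicit mask, never a numeric
#' sentinel).
#'
#' @param values numeric matrix, genes (or probes) in rows and samples in
#'   columns. `rownames` are the probe/gene identifiers, `colnames` the sample
#'   ids. Missing cells are `NA`.
#' @param samples data.frame with one row per column of `values`; required
#'   columns `sample_id`, `tissue`, `age` (numeric, months or days), optional
#'   `sex`, `replicate`, `dataset`. Rows are re-ordered to match the column
#'   order of `values`.
#' @param scale `"log2"` or `"linear"`; the scale the values are stored on.
#' @param detection optional character matrix of detection calls (`"P"`,
#'   `"A"`, `"M"`) with the same dimensions and dimnames as `values`.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `samples`, `scale`, `detection`.
#' @seealso [load_expression()], [filter_missing_probes()],
#'   [collapse_duplicate_probes()]
#' @export
#' @examples
#' vals <- matrix(rnorm(6, 8), nrow = 2,
#'                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ann <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                   tissue = c("A", "A", "B"), age = c(4, 10, 4))
#' ds <- expression_dataset(vals, ann, scale = "log2")
expression_dataset <- function(values, samples, scale = c("log2", "linear"),
                               detection = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) stop("values matrix must carry gene ids as rownames")
  if (is.null(colnames(values))) stop("values matrix must carry sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe/gene identifiers in values matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in values matrix")

  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue", "age")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample annotations lack column(s): ", paste(missing_cols, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids in annotations")
  unknown <- setdiff(colnames(values), samples$sample_id)
  if (length(unknown))
    stop("samples present in matrix but absent from annotations: ",
         paste(unknown, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$tissue <- as.character(samples$tissue)
  suppressWarnings(samples$age <- as.numeric(samples$age))
  if (anyNA(samples$age)) stop("non-numeric age in annotations")

  if (!is.null(detection)) {
    detection <- as.matrix(detection)
    if (!identical(dim(detection), dim(values)))
      stop("detection call matrix dimensions differ from values")
    if (!is.null(colnames(detection)) &&
        !identical(colnames(detection), colnames(values)))
      detection <- detection[, colnames(values), drop = FALSE]
    if (!is.null(rownames(detection)) &&
        !identical(rownames(detection), rownames(values)))
      detection <- detection[rownames(values), , drop = FALSE]
    dimnames(detection) <- dimnames(values)
    bad <- !is.na(detection) & !(detection %in% c("P", "A", "M"))
    if (any(bad)) stop("detection calls must be P, A or M")
  }

  structure(list(values = values, samples = samples, scale = scale,
                 detection = detection),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  tissues: %s\n", paste(unique(x$samples$tissue), collapse = ", ")))
  cat(sprintf("  ages:    %s\n", paste(format_age(age_ladder(x)), collapse = ", ")))
  cat(sprintf("  missing values: %d; detection calls: %s\n",
              n_missing(x), if (is.null(x$detection)) "none" else "present"))
  invisible(x)
}

#' Number of missing (masked) measurements in a dataset
#' @param ds an `ExpressionDataset`
#' @return integer count of `NA` cells in the value matrix
#' @export
n_missing <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  sum(is.na(ds$values))
}

#' Ordered age ladder of a dataset
#' @param ds an `ExpressionDataset`
#' @return sorted numeric vector of the distinct ages present
#' @export
age_ladder <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  sort(unique(ds$samples$age))
}

# subset a dataset to a set of row indices (internal; keeps class invariants)
subset_genes <- function(ds, idx) {
  ds$values <- ds$values[idx, , drop = FALSE]
  if (!is.null(ds$detection)) ds$detection <- ds$detection[idx, , drop = FALSE]
  ds
}

#' Read an expression matrix and sample annotations from TSV files
#'
#' The matrix file is tab-delimited with a header row of sample ids and a
#' first column of probe/gene identifiers; missing measurements are encoded
#' by a sentinel token (default `"NA"`). The annotation file maps every
#' sample id to its tissue and age (plus optional sex/replicate/dataset).
#' Values are read verbatim: no transformation is applied, and the declared
#' `scale` is simply recorded on the returned dataset.
#'
#' @param matrix_path path to the expression matrix TSV
#' @param annotation_path path to the sample annotation TSV (columns
#'   `sample_id`, `tissue`, `age`, and optionally `sex`, `replicate`,
#'   `dataset`)
#' @param scale the scale values are stored on, `"log2"` or `"linear"`
#' @param detection_path optional path to a detection-call TSV of identical
#'   shape to the matrix, with cells in `P`/`A`/`M`
#' @param missing_marker token encoding a missing value in the files
#' @return an [expression_dataset()]
#' @export
load_expression <- function(matrix_path, annotation_path,
                            scale = c("log2", "linear"),
                            detection_path = NULL, missing_marker = "NA") {
  scale <- match.arg(scale)
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (ncol(raw) < 2) stop("expression matrix needs a gene-id column and >= 1 sample")
  ids <- raw[[1]]
  chr <- as.matrix(raw[, -1, drop = FALSE])
  chr[chr == missing_marker] <- NA
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- which(!is.na(chr) & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric cell that is not the missing marker: gene '%s', sample '%s', value '%s'",
      ids[bad[1, 1]], colnames(chr)[bad[1, 2]], chr[bad[1, 1], bad[1, 2]]))
  }
  rownames(num) <- ids
  colnames(num) <- colnames(chr)

  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE)

  detection <- NULL
  if (!is.null(detection_path)) {
    draw <- utils::read.delim(detection_path, check.names = FALSE,
                              colClasses = "character", na.strings = missing_marker)
    detection <- as.matrix(draw[, -1, drop = FALSE])
    rownames(detection) <- draw[[1]]
  }

  expression_dataset(num, ann, scale = scale, detection = detection)
}

#' Write a dataset back to the standard TSV files
#'
#' Inverse of [load_expression()]: values are printed with full (15
#' significant digit) precision so that a write/read round trip preserves
#' them to printed precision.
#'
#' @param ds an `ExpressionDataset`
#' @param matrix_path,annotation_path,detection_path output paths;
#'   `detection_path` is only used when the dataset carries detection calls
#' @param missing_marker token to write for missing values
#' @return invisibly, the paths written
#' @export
write_expression <- function(ds, matrix_path, annotation_path,
                             detection_path = NULL, missing_marker = "NA") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  fmt <- ifelse(is.na(ds$values), missing_marker,
                sprintf("%.15g", ds$values))
  dim(fmt) <- dim(ds$values)
  out <- data.frame(gene_id = rownames(ds$values), fmt,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(ds$values))
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$samples, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  paths <- c(matrix_path, annotation_path)
  if (!is.null(ds$detection) && !is.null(detection_path)) {
    det <- data.frame(gene_id = rownames(ds$detection), ds$detection,
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(det) <- c("gene_id", colnames(ds$detection))
    utils::write.table(det, detection_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = missing_marker)
    paths <- c(paths, detection_path)
  }
  invisible(paths)
}

#' Remove probes with too many missing measurements
#'
#' Probes whose missing fraction is strictly greater than
#' `max_missing_fraction` are removed; a probe missing in exactly that
#' fraction of samples survives. Row order of retained probes is preserved,
#' and the operation is idempotent.
#'
#' @param ds an `ExpressionDataset`
#' @param max_missing_fraction proportion in `[0, 1]`; default 0.80
#' @return the filtered dataset (possibly with zero rows)
#' @export
filter_missing_probes <- function(ds, max_missing_fraction = 0.80) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            is.numeric(max_missing_fraction),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(ds$values))
  subset_genes(ds, which(frac <= max_missing_fraction))
}

#' Collapse duplicate probes to one probe per gene
#'
#' When several probes map to the same gene, the probe measured (non-missing)
#' in the largest number of samples is retained. Ties are broken by input row
#' order: the probe appearing first in the matrix wins. Retained rows keep
#' their relative input order and are renamed to the gene identifier.
#'
#' @param ds an `ExpressionDataset` whose rownames are probe ids
#' @param gene_map probe-to-gene mapping: either a named character vector
#'   (names = probe ids) or a data.frame with columns `probe` and `gene`.
#'   Must cover every probe in `ds`.
#' @return dataset with one row per gene, rownames = gene ids
#' @export
collapse_duplicate_probes <- function(ds, gene_map) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.data.frame(gene_map)) {
    stopifnot(all(c("probe", "gene") %in% names(gene_map)))
    gene_map <- stats::setNames(as.character(gene_map$gene),
                                as.character(gene_map$probe))
  }
  probes <- rownames(ds$values)
  uncovered <- setdiff(probes, names(gene_map))
  if (length(uncovered))
    stop("gene_map does not cover probe(s): ", paste(uncovered, collapse = ", "))
  gene <- unname(gene_map[probes])
  presented <- rowSums(!is.na(ds$values))
  # which.max returns the first maximum, giving the lowest-row-index tie-break
  pick <- vapply(split(seq_along(probes), gene)[unique(gene)],
                 function(idx) idx[which.max(presented[idx])],
                 integer(1))
  pick <- sort(pick)  # preserve input order among retained probes
  out <- subset_genes(ds, pick)
  rownames(out$values) <- gene[pick]
  if (!is.null(out$detection)) rownames(out$detection) <- gene[pick]
  out
}
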