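#' Construct an expression matrix object
#'
#' An `ExpressionMatrix` bundles a genes-by-samples numeric matrix with the
#' metadata the meta-analysis needs: which dataset it came from, whether the
#' values are sequencing counts or array-style intensities, and which
#' phenotype group (low- or high-androstenone, `"LA"`/`"HA"`) the samples
#' belong to.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Counts must be
#'   non-negative integers when `platform = "count"`.
#' @param dataset_id single string identifying the source dataset.
#' @param platform `"count"` (RNA-seq-like) or `"intensity"`
#'   (microarray-like).
#' @param phenotype `"LA"` or `"HA"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, dataset_id, platform, phenotype) {
  platform <- match.arg(platform, PLATFORMS)
  phenotype <- match.arg(phenotype, PHENOTYPES)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("'values' must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    stopf("'values' contains missing entries")
  if (platform == "count") {
    if (any(values < 0) || any(values != round(values)))
      stopf("count platform requires non-negative integer values")
  }
  structure(
    list(values = values, dataset_id = as.character(dataset_id),
         platform = platform, phenotype = phenotype),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix '%s' [%s, %s]: %d genes x %d samples\n",
              x$dataset_id, x$platform, x$phenotype,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

gene_ids <- function(em) rownames(em$values)
sample_ids <- function(em) colnames(em$values)

#' Read an expression matrix from delimited text
#'
#' Expects tab-separated text with a header row of sample ids and the gene
#' (or probe) id in the first column. Every remaining cell must be numeric;
#' a non-numeric cell or a duplicated id aborts the load with a message
#' naming the offending row.
#'
#' @inheritParams expression_matrix
#' @param path path to a TSV file.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, dataset_id, platform, phenotype) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stopf("'%s': need an id column plus at least one sample", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stopf("'%s': duplicated gene id '%s'", path, ids[duplicated(ids)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("'%s': non-numeric cell in row for gene '%s' (column '%s')",
          path, ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]])
  if (anyNA(num))
    stopf("'%s': missing value in row for gene '%s'",
          path, ids[which(is.na(num), arr.ind = TRUE)[1L, 1L]])
  dimnames(num) <- list(ids, colnames(vals))
  expression_matrix(num, dataset_id, platform, phenotype)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are serialised at full double precision so that
#' `read_expression(write_expression(x))` reproduces them to at least 12
#' significant digits.
#'
#' @param em an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  txt <- apply(em$values, c(1, 2), fmt_num)
  df <- data.frame(gene_id = gene_ids(em), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", sample_ids(em))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV (`probe_id`, `gene_id`). Many probes may map to one gene;
#' a probe mapping to more than one gene is an error.
#'
#' @param path TSV path.
#' @return A `ProbeMap`: named character vector, `names` = probe ids,
#'   values = gene ids.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  probe_map(df[[1L]], df[[2L]])
}

#' @rdname read_probe_map
#' @param probe_id,gene_id character vectors of equal length.
#' @export
probe_map <- function(probe_id, gene_id) {
  if (length(probe_id) != length(gene_id))
    stopf("probe and gene vectors differ in length")
  if (anyDuplicated(probe_id))
    stopf("probe '%s' maps to more than one gene",
          probe_id[duplicated(probe_id)][1L])
  structure(setNames(as.character(gene_id), as.character(probe_id)),
            class = "ProbeMap")
}
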