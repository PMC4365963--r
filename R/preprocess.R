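#' Log counts-per-million transform
#'
#' Converts a count matrix to log2 counts-per-million:
#' `log2((count + prior) / (lib_size + 2 * prior) * 1e6)`, where `lib_size`
#' is the sample's column sum. The prior count keeps all-zero genes finite.
#' Precision weights (voom-style mean-variance modelling) are deliberately
#' not computed: downstream the matrix is only consumed through per-gene
#' Pearson correlations, which do not use observation weights.
#'
#' @param counts an [expression_matrix()] with `platform = "count"`.
#' @param prior_count prior count added to each observation (default 0.5).
#' @return An intensity-platform [expression_matrix()].
#' @export
log_cpm <- function(counts, prior_count = 0.5) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$platform != "count") stopf("log_cpm requires a count matrix")
  lib <- colSums(counts$values)
  if (any(lib == 0)) stopf("sample(s) with zero library size: %s",
                           paste(colnames(counts$values)[lib == 0], collapse = ", "))
  v <- log2(sweep(counts$values + prior_count, 2L, lib + 2 * prior_count, "/") * 1e6)
  expression_matrix(v, counts$dataset_id, "intensity", counts$phenotype)
}

#' Collapse probe rows to one row per gene by largest variance
#'
#' When several probes map to the same gene, the probe whose values have
#' the largest between-sample variance (unbiased, n - 1 denominator)
#' represents the gene; the remaining probe rows are discarded. Variance
#' ties are broken by the lexicographically smallest probe id. Probes
#' absent from the map are dropped with a message.
#'
#' @param m an [expression_matrix()] whose rows are probe ids.
#' @param pm a [probe_map()].
#' @return An [expression_matrix()] with one row per gene, rows sorted by
#'   gene id.
#' @export
collapse_probes <- function(m, pm) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(pm, "ProbeMap"))
  probes <- intersect(gene_ids(m), names(pm))
  if (length(probes) == 0L) stopf("no probe of the matrix occurs in the map")
  n_drop <- nrow(m$values) - length(probes)
  if (n_drop > 0L) message(sprintf("collapse_probes: dropped %d unmapped probe(s)", n_drop))
  vals <- m$values[probes, , drop = FALSE]
  vr <- apply(vals, 1L, var)
  ord <- order(unname(pm[probes]), -vr, probes)
  gene_of <- unname(pm[probes])[ord]
  keep <- ord[!duplicated(gene_of)]
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- unname(pm[probes])[keep]
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out, m$dataset_id, m$platform, m$phenotype)
}

#' Restrict matrices to their common gene set
#'
#' Keeps only genes present in every matrix, in sorted order, so that all
#' outputs share an identical gene universe. Idempotent.
#'
#' @param matrices list of at least two [expression_matrix()] objects.
#' @return list of matrices restricted to the sorted common genes.
#' @export
intersect_genes <- function(matrices) {
  if (length(matrices) < 2L) stopf("need at least two matrices")
  common <- sort(Reduce(intersect, lapply(matrices, gene_ids)))
  if (length(common) == 0L) stopf("no gene common to all matrices")
  lapply(matrices, function(m)
    expression_matrix(m$values[common, , drop = FALSE],
                      m$dataset_id, m$platform, m$phenotype))
}

#' Bundle same-phenotype matrices over one gene universe
#'
#' @param phenotype `"LA"` or `"HA"`.
#' @param matrices list of [expression_matrix()] objects with this
#'   phenotype, all sharing the same ordered gene ids.
#' @return A `PhenotypeSet` object.
#' @export
phenotype_set <- function(phenotype, matrices) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  if (length(matrices) == 0L) stopf("empty phenotype set")
  g0 <- gene_ids(matrices[[1L]])
  for (m in matrices) {
    if (m$phenotype != phenotype) stopf("matrix '%s' has phenotype %s, expected %s",
                                        m$dataset_id, m$phenotype, phenotype)
    if (!identical(gene_ids(m), g0))
      stopf("matrix '%s' disagrees on the gene universe", m$dataset_id)
  }
  ids <- vapply(matrices, `[[`, "", "dataset_id")
  if (anyDuplicated(ids)) stopf("duplicate dataset ids in phenotype set")
  structure(list(phenotype = phenotype, matrices = setNames(matrices, ids)),
            class = "PhenotypeSet")
}

#' @export
print.PhenotypeSet <- function(x, ...) {
  cat(sprintf("PhenotypeSet %s: %d datasets (%s), %d genes\n", x$phenotype,
              length(x$matrices), paste(names(x$matrices), collapse = ", "),
              nrow(x$matrices[[1L]]$values)))
  invisible(x)
}

#' Split matrices into LA and HA phenotype sets
#'
#' Matrices are first restricted to their common gene universe, then
#' grouped by their phenotype label. The cross-dataset joint CDF needs at
#' least two datasets per phenotype; a single-dataset group is an error
#' unless `allow_single = TRUE`.
#'
#' @param matrices list of [expression_matrix()] objects labelled LA or HA.
#' @param allow_single permit a phenotype group with one matrix.
#' @return Named list with elements `LA` and `HA`, each a
#'   [phenotype_set()].
#' @export
group_by_phenotype <- function(matrices, allow_single = FALSE) {
  matrices <- intersect_genes(matrices)
  out <- lapply(PHENOTYPES, function(ph) {
    ms <- Filter(function(m) m$phenotype == ph, matrices)
    if (length(ms) == 0L) return(NULL)
    if (length(ms) < 2L && !allow_single)
      stopf("phenotype %s has %d matrix; need >= 2 (set allow_single to override)",
            ph, length(ms))
    phenotype_set(ph, ms)
  })
  setNames(out, PHENOTYPES)
}
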