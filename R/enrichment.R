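#' One-sided Fisher exact test for over-representation
#'
#' For the 2x2 table `a` (in cluster, annotated), `b` (not in cluster,
#' annotated), `c` (in cluster, not annotated), `d` (neither), returns
#' the exact upper hypergeometric tail `P(X >= a)` with the table's
#' margins fixed — the one-sided Fisher p-value for over-representation.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0) || any(cnt != round(cnt))) stopf("counts must be non-negative integers")
  # X ~ Hypergeometric(N = a+b+c+d, white = a+b, drawn = a+c)
  phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

term_gene_sets <- function(ann) split(ann$gene_id, ann$term_id)

enrich_test <- function(cluster, background, genes_t) {
  genes_t <- intersect(genes_t, background)
  a <- length(intersect(cluster, genes_t))
  b <- length(genes_t) - a
  c_ <- length(cluster) - a
  d <- length(background) - length(cluster) - b
  fisher_exact(a, b, c_, d)
}

#' Hierarchy-aware GO enrichment of a gene cluster
#'
#' Tests every biological-process term annotating at least one background
#' gene with the one-sided Fisher test. `algorithm = "classic"` tests each
#' term independently. `algorithm = "elim"` decorrelates the DAG: terms
#' are processed deepest level first (ties broken by ascending term id);
#' when a term's p-value falls below `elim_alpha`, the cluster genes it
#' annotates are removed from all its ancestors before those are tested,
#' so a parent is not called enriched merely because of a significant
#' child. Annotations are up-propagated (true-path rule) before testing.
#' Reported terms satisfy `p < p_cutoff` and annotate at least
#' `min_genes` cluster genes.
#'
#' @param cluster character vector of cluster gene ids (must all be in
#'   `background`).
#' @param background character vector: the gene universe.
#' @param dag an [ontology_graph()].
#' @param ann an [annotation_table()] of gene-to-GO annotations.
#' @param algorithm `"elim"` (default) or `"classic"`.
#' @param elim_alpha elimination threshold for the elim pass (default 0.01).
#' @param p_cutoff,min_genes reporting filters (defaults 0.05 and 5).
#' @param namespace ontology namespace tested (default
#'   `"biological_process"`).
#' @return data.frame of class `EnrichmentResult`: `term_id`, `name`,
#'   `n_genes` (cluster genes annotated), `p_value`, `genes`
#'   (comma-separated), sorted by p-value.
#' @export
go_enrich <- function(cluster, background, dag, ann,
                      algorithm = c("elim", "classic"), elim_alpha = 0.01,
                      p_cutoff = 0.05, min_genes = 5L,
                      namespace = "biological_process") {
  algorithm <- match.arg(algorithm)
  if (!all(cluster %in% background))
    stopf("cluster gene(s) absent from background: %s",
          paste(head(setdiff(cluster, background), 3L), collapse = ", "))
  ann <- propagate_annotations(ann, dag)
  ann <- ann[ann$gene_id %in% background, , drop = FALSE]
  ns_terms <- dag$terms$id[dag$terms$namespace == namespace]
  ann <- ann[ann$term_id %in% ns_terms, , drop = FALSE]
  t2g <- term_gene_sets(ann)
  if (length(t2g) == 0L) return(empty_enrichment())

  depths <- term_depths(dag)
  terms <- names(t2g)
  ord <- order(-depths[terms], terms)   # deepest first, then term id
  terms <- terms[ord]

  removed <- setNames(vector("list", length(terms)), terms)
  pvals <- setNames(numeric(length(terms)), terms)
  for (t in terms) {
    eff <- setdiff(t2g[[t]], removed[[t]])
    pvals[t] <- enrich_test(cluster, background, eff)
    if (algorithm == "elim" && pvals[t] < elim_alpha) {
      hit <- intersect(intersect(t2g[[t]], cluster), eff)
      if (length(hit) > 0L) {
        anc <- setdiff(term_ancestors(dag, t), t)
        for (a_ in intersect(anc, terms))
          removed[[a_]] <- union(removed[[a_]], hit)
      }
    }
  }
  build_enrichment(cluster, t2g, pvals, dag$terms, p_cutoff, min_genes)
}

#' Flat pathway enrichment of a gene cluster
#'
#' One-sided Fisher test per pathway against the background universe,
#' with the same reporting filters as [go_enrich()]; no hierarchy is
#' assumed.
#'
#' @inheritParams go_enrich
#' @param pathway_map an [annotation_table()] of gene-to-pathway
#'   annotations.
#' @return an `EnrichmentResult` data.frame.
#' @export
pathway_enrich <- function(cluster, background, pathway_map,
                           p_cutoff = 0.05, min_genes = 5L) {
  if (!all(cluster %in% background))
    stopf("cluster gene(s) absent from background: %s",
          paste(head(setdiff(cluster, background), 3L), collapse = ", "))
  pm <- pathway_map[pathway_map$gene_id %in% background, , drop = FALSE]
  t2g <- term_gene_sets(pm)
  if (length(t2g) == 0L) return(empty_enrichment())
  pvals <- vapply(t2g, function(g) enrich_test(cluster, background, g), 0)
  names_df <- data.frame(id = names(t2g), name = names(t2g),
                         stringsAsFactors = FALSE)
  build_enrichment(cluster, t2g, pvals, names_df, p_cutoff, min_genes)
}

empty_enrichment <- function() {
  out <- data.frame(term_id = character(0), name = character(0),
                    n_genes = integer(0), p_value = numeric(0),
                    genes = character(0), stringsAsFactors = FALSE)
  class(out) <- c("EnrichmentResult", class(out))
  out
}

build_enrichment <- function(cluster, t2g, pvals, term_info, p_cutoff,
                             min_genes) {
  hits <- lapply(t2g[names(pvals)], intersect, x = cluster)
  n <- vapply(hits, length, 0L)
  keep <- pvals < p_cutoff & n >= min_genes
  out <- data.frame(
    term_id = names(pvals)[keep],
    name = term_info$name[match(names(pvals)[keep], term_info$id)],
    n_genes = n[keep],
    p_value = unname(pvals[keep]),
    genes = vapply(hits[keep], function(g) paste(sort(g), collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", class(out))
  out
}

#' Write an enrichment table as TSV
#' @param res an `EnrichmentResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
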