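#' Hypergeometric overlap test between two gene clusters
#'
#' Physical similarity: the probability of observing at least the actual
#' overlap `k = |A intersect B|` when `|B|` genes are drawn without
#' replacement from a universe of `universe_size` genes of which `|A|`
#' are marked.
#'
#' @param a,b character vectors of gene ids.
#' @param universe_size size of the shared gene universe (>= both
#'   cluster sizes).
#' @return list with `overlap` (k) and `p_value` (upper tail, `P(X >= k)`).
#' @export
hypergeom_overlap <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  if (length(a) > universe_size || length(b) > universe_size)
    stopf("cluster larger than the universe")
  k <- length(intersect(a, b))
  p <- phyper(k - 1, length(a), universe_size - length(a), length(b),
              lower.tail = FALSE)
  list(overlap = k, p_value = p)
}

wang_weights <- function(w_is_a, w_part_of)
  c(is_a = w_is_a, part_of = w_part_of)

#' Semantic contributions (S-values) of a term's ancestor closure
#'
#' The term itself contributes 1; each ancestor `t` contributes
#' `max over closure-children c of w(edge) * S(c)`, with edge weights
#' 0.8 for `is_a` and 0.6 for `part_of` by default. Computed iteratively
#' in reverse topological order of the closure.
#'
#' @inheritParams wang_similarity
#' @param term a primary term id.
#' @return named numeric vector of S-values over the ancestor closure.
#' @export
wang_svalues <- function(term, dag, w_is_a = 0.8, w_part_of = 0.6) {
  term <- resolve_terms(dag, term)
  if (!term %in% dag$terms$id) stopf("unknown term '%s'", term)
  closure <- term_ancestors(dag, term)
  ed <- dag$edges[dag$edges$child %in% closure &
                  dag$edges$parent %in% closure, , drop = FALSE]
  w <- wang_weights(w_is_a, w_part_of)[ed$relation]
  s <- setNames(numeric(length(closure)), closure)
  s[term] <- 1
  # children before parents: order closure by decreasing depth
  dp <- term_depths(dag)[closure]
  for (t in closure[order(-dp)]) {
    if (t == term) next
    ci <- which(ed$parent == t)
    if (length(ci) > 0L)
      s[t] <- max(w[ci] * s[ed$child[ci]])
  }
  s
}

#' Wang graph-based semantic similarity of two ontology terms
#'
#' `sim(A, B) = sum over shared closure terms of (S_A(t) + S_B(t))`
#' divided by `(SV(A) + SV(B))`, where `SV` is the total semantic value
#' (sum of S-values). Symmetric, in \[0, 1\], and 1 exactly for identical
#' terms.
#'
#' @param term_a,term_b term ids.
#' @param dag an [ontology_graph()].
#' @param w_is_a,w_part_of semantic edge weights (defaults 0.8 and 0.6).
#' @return similarity in \[0, 1\].
#' @export
wang_similarity <- function(term_a, term_b, dag, w_is_a = 0.8,
                            w_part_of = 0.6) {
  sa <- wang_svalues(term_a, dag, w_is_a, w_part_of)
  sb <- wang_svalues(term_b, dag, w_is_a, w_part_of)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L) return(0)
  unname(sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb)))
}

#' Pairwise Wang similarity matrix between two term sets
#'
#' @param terms_a,terms_b character vectors of term ids.
#' @inheritParams wang_similarity
#' @param svalue_cache optional pre-computed list of S-value vectors
#'   keyed by term id (see [wang_svalues()]).
#' @return numeric matrix `length(terms_a) x length(terms_b)`.
#' @export
wang_sim_matrix <- function(terms_a, terms_b, dag, w_is_a = 0.8,
                            w_part_of = 0.6, svalue_cache = NULL) {
  if (length(terms_a) == 0L || length(terms_b) == 0L)
    stopf("empty term set")
  all_terms <- unique(c(terms_a, terms_b))
  cache <- svalue_cache %||%
    setNames(lapply(all_terms, wang_svalues, dag = dag, w_is_a = w_is_a,
                    w_part_of = w_part_of), all_terms)
  sim1 <- function(x, y) {
    sa <- cache[[x]]; sb <- cache[[y]]
    shared <- intersect(names(sa), names(sb))
    if (length(shared) == 0L) return(0)
    sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
  }
  m <- outer(seq_along(terms_a), seq_along(terms_b),
             Vectorize(function(i, j) sim1(terms_a[i], terms_b[j])))
  dimnames(m) <- list(terms_a, terms_b)
  m
}

#' Best-match average of a similarity matrix
#'
#' `(sum of row maxima + sum of column maxima) / (nrow + ncol)` — the BMA
#' combination of a term-set similarity matrix into a single cluster
#' similarity value (`sim_CLUS`).
#'
#' @param m numeric matrix of similarities in \[0, 1\].
#' @return scalar in \[0, 1\].
#' @export
bma_combine <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L) stopf("empty similarity matrix")
  (sum(apply(m, 1L, max)) + sum(apply(m, 2L, max))) / (nrow(m) + ncol(m))
}

#' Null distribution of cluster functional similarity
#'
#' Repeats `n` times: draw two set sizes uniformly from the observed
#' enriched-set sizes, sample two term sets of those sizes without
#' replacement from the annotation term pool, and record their Wang + BMA
#' similarity (`sim_RAND`). The pairwise similarity matrix over the pool
#' is computed once, so large `n` is cheap.
#'
#' @param pool character vector of candidate terms (all ontology terms
#'   annotated to at least one background gene).
#' @param sizes integer vector of observed enriched-set sizes to draw
#'   from.
#' @param n number of repetitions (>= 100; the study-scale default is
#'   10,000).
#' @param seed RNG seed.
#' @inheritParams wang_similarity
#' @return A `NullSimSample`: list with `values` (length `n`), `n`,
#'   `seed`.
#' @export
sample_null <- function(pool, sizes, n = 10000L, seed = 1L, dag,
                        w_is_a = 0.8, w_part_of = 0.6) {
  pool <- unique(pool)
  if (length(pool) == 0L) stopf("empty term pool")
  if (length(sizes) == 0L) stopf("no observed set sizes")
  if (n < 100L) stopf("n must be >= 100")
  if (max(sizes) > length(pool)) stopf("requested size exceeds the pool")
  big <- wang_sim_matrix(pool, pool, dag, w_is_a, w_part_of)
  vals <- withr::with_seed(seed, vapply(seq_len(n), function(i) {
    s1 <- sample(sizes, 1L); s2 <- sample(sizes, 1L)
    i1 <- sample.int(length(pool), s1)
    i2 <- sample.int(length(pool), s2)
    bma_combine(big[i1, i2, drop = FALSE])
  }, 0))
  structure(list(values = vals, n = n, seed = seed),
            class = "NullSimSample")
}

#' Empirical p-value of a cluster similarity against its null
#'
#' `p = #\{sim_RAND > sim_CLUS\} / N` — ties do not count against
#' significance.
#'
#' @param sim_clus observed cluster similarity.
#' @param null a `NullSimSample` from [sample_null()].
#' @return p-value in \[0, 1\].
#' @export
empirical_pvalue <- function(sim_clus, null) {
  stopifnot(inherits(null, "NullSimSample"), length(null$values) > 0L)
  sum(null$values > sim_clus) / length(null$values)
}

#' Physical and functional cluster similarity graphs
#'
#' Physical similarity (hypergeometric membership overlap) is tested for
#' every LA-versus-HA cluster pair only, since clusters within one
#' partition are disjoint by construction. Functional similarity
#' (Wang + BMA over enriched GO terms, with an empirical null) is tested
#' for every pair of GO-enriched clusters, including within-phenotype
#' pairs. Only significant edges (`p < alpha`) enter the graphs.
#'
#' @param la_clusters,ha_clusters lists of scored clusters
#'   (see [score_clusters()]).
#' @param enrichments named list: for each cluster id, its GO
#'   `EnrichmentResult` (clusters without GO enrichment are skipped in
#'   the functional graph).
#' @param universe_size gene-universe size for the hypergeometric test.
#' @param dag an [ontology_graph()] (functional graph only).
#' @param null a `NullSimSample` (functional graph only).
#' @param alpha significance level (default 0.05).
#' @return list with `physical` and `functional` igraph graphs plus the
#'   full test tables `physical_table`, `functional_table`.
#' @export
similarity_graphs <- function(la_clusters, ha_clusters, enrichments = list(),
                              universe_size, dag = NULL, null = NULL,
                              alpha = 0.05) {
  cl_ids <- function(cls) vapply(cls, `[[`, "", "cluster_id")
  # --- physical: LA x HA only
  ptab <- data.frame()
  for (a in la_clusters) for (b in ha_clusters) {
    h <- hypergeom_overlap(a$genes, b$genes, universe_size)
    ptab <- rbind(ptab, data.frame(
      cluster_a = a$cluster_id, cluster_b = b$cluster_id,
      size_a = length(a$genes), size_b = length(b$genes),
      overlap = h$overlap, p_value = h$p_value, stringsAsFactors = FALSE))
  }
  phys <- graph_from_table(ptab, c(cl_ids(la_clusters), cl_ids(ha_clusters)),
                           alpha, "overlap")
  # --- functional: all pairs of GO-enriched clusters
  ftab <- data.frame()
  enriched <- names(enrichments)[vapply(enrichments, nrow, 0L) > 0L]
  all_cl <- c(la_clusters, ha_clusters)
  names(all_cl) <- cl_ids(all_cl)
  if (length(enriched) >= 2L && !is.null(dag) && !is.null(null)) {
    combs <- utils::combn(sort(enriched), 2L)
    for (j in seq_len(ncol(combs))) {
      ta <- enrichments[[combs[1L, j]]]$term_id
      tb <- enrichments[[combs[2L, j]]]$term_id
      sim <- bma_combine(wang_sim_matrix(ta, tb, dag))
      ftab <- rbind(ftab, data.frame(
        cluster_a = combs[1L, j], cluster_b = combs[2L, j],
        sim_clus = sim, p_value = empirical_pvalue(sim, null),
        stringsAsFactors = FALSE))
    }
  }
  func <- graph_from_table(ftab, enriched, alpha, "sim_clus")
  list(physical = phys, functional = func,
       physical_table = ptab, functional_table = ftab)
}

graph_from_table <- function(tab, nodes, alpha, label_col) {
  nodes <- as.character(nodes %||% character(0))
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(tab) == 0L) return(g)
  sig <- tab[tab$p_value < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) return(g)
  g <- igraph::add_edges(g, rbind(match(sig$cluster_a, nodes),
                                  match(sig$cluster_b, nodes)))
  igraph::E(g)$label <- sig[[label_col]]
  igraph::E(g)$p_value <- sig$p_value
  g
}
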