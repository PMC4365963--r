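#' Pearson correlations for all unordered gene pairs
#'
#' Computes the Pearson correlation of every unordered gene pair
#' (`n * (n - 1) / 2` pairs for `n` genes). Genes with zero variance
#' across samples cannot be correlated and are dropped with a warning.
#'
#' @param m an [expression_matrix()] with at least 3 samples.
#' @return data.frame with columns `gene1`, `gene2` (gene1 < gene2 in the
#'   matrix's row order) and `r`.
#' @export
pearson_pairs <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 3L) stopf("need at least 3 samples to correlate")
  vr <- apply(m$values, 1L, var)
  if (any(vr == 0)) {
    warnf("dropping %d zero-variance gene(s)", sum(vr == 0))
    m <- expression_matrix(m$values[vr > 0, , drop = FALSE],
                           m$dataset_id, m$platform, m$phenotype)
  }
  cc <- cor(t(m$values))
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  data.frame(gene1 = rownames(cc)[ut[, 1L]],
             gene2 = rownames(cc)[ut[, 2L]],
             r = cc[ut], stringsAsFactors = FALSE)
}

#' Absolute rank-order ratios of correlations
#'
#' Ranks pairs ascending on the absolute value of their correlation
#' (rank 1 = weakest co-expression, ties get the average rank) and divides
#' by the number of pairs, so a ratio near 1 marks the strongest
#' co-expression in that dataset regardless of sign.
#'
#' @param r numeric vector of correlations.
#' @return numeric vector of rank ratios in (0, 1].
#' @export
rank_ratios <- function(r) {
  if (length(r) == 0L) stopf("empty correlation vector")
  rank(abs(r), ties.method = "average") / length(r)
}

#' Joint CDF of uniform order statistics
#'
#' The cross-dataset co-expression weight of a gene pair: the probability
#' that the i-th smallest of `n` independent Uniform(0,1) variables is at
#' most the i-th smallest supplied rank ratio, for every i. Ratios are
#' sorted ascending and the nested integral
#' `n! * int_0^{r1} int_{s1}^{r2} ... int_{s_{n-1}}^{r_n} ds_n ... ds_1`
#' is evaluated exactly by iterated polynomial integration, carrying the
#' polynomial coefficients from the innermost integral outward.
#'
#' @param ratios numeric vector of 1 to 10 values in \[0, 1\].
#' @return joint cumulative probability in \[0, 1\].
#' @export
joint_cdf <- function(ratios) {
  n <- length(ratios)
  if (n < 1L || n > 10L) stopf("joint_cdf supports 1 to 10 ratios")
  if (anyNA(ratios) || any(ratios < 0) || any(ratios > 1))
    stopf("rank ratios must lie in [0, 1]")
  r <- sort(ratios)
  # p holds coefficients of the current integrand polynomial in the next
  # integration variable, constant term first
  p <- 1
  for (k in n:1) {
    antider <- c(0, p / seq_along(p))        # term-wise antiderivative
    upper <- sum(antider * r[k]^(seq_along(antider) - 1L))
    p <- c(upper, -antider[-1L])             # upper - antider(s_{k-1})
  }
  # after the outermost step (lower limit 0) only the constant survives
  unname(factorial(n) * p[1L])
}

#' Per-phenotype pair table: correlations and rank ratios per dataset
#'
#' For every unordered gene pair of the common gene universe, records each
#' dataset's Pearson correlation (`cor.<dataset_id>`) and absolute
#' rank-order ratio (`ratio.<dataset_id>`).
#'
#' @param pset a [phenotype_set()].
#' @return data.frame of class `PairTable`.
#' @export
pair_table <- function(pset) {
  stopifnot(inherits(pset, "PhenotypeSet"))
  tabs <- lapply(pset$matrices, pearson_pairs)
  base <- tabs[[1L]][, c("gene1", "gene2")]
  for (i in seq_along(tabs)) {
    if (!identical(tabs[[i]][, 1:2], base))
      stopf("datasets disagree on the pair universe (zero-variance genes?)")
  }
  out <- base
  for (id in names(tabs)) {
    out[[paste0("cor.", id)]] <- tabs[[id]]$r
    out[[paste0("ratio.", id)]] <- rank_ratios(tabs[[id]]$r)
  }
  attr(out, "phenotype") <- pset$phenotype
  attr(out, "dataset_ids") <- names(tabs)
  class(out) <- c("PairTable", class(out))
  out
}

#' Prune gene pairs on signed correlation
#'
#' A pair is retained only if its signed correlation exceeds `threshold`
#' in every dataset of the phenotype; this removes both weak pairs and
#' pairs with conflicting correlation sign across datasets.
#'
#' @param pt a [pair_table()].
#' @param threshold retention threshold; pairs with any correlation
#'   `<= threshold` are trimmed (default +0.50).
#' @return The retained subset of `pt`.
#' @export
prune_pairs <- function(pt, threshold = 0.5) {
  cors <- as.matrix(pt[, grep("^cor\\.", names(pt)), drop = FALSE])
  keep <- rowSums(cors > threshold) == ncol(cors)
  out <- pt[keep, , drop = FALSE]
  attributes(out)[c("phenotype", "dataset_ids")] <-
    attributes(pt)[c("phenotype", "dataset_ids")]
  out
}

#' Build the weighted co-expression network
#'
#' Nodes are the genes incident to at least one retained pair; each edge
#' carries the per-dataset correlations (`cor_<dataset_id>`) and the joint
#' CDF of the pair's rank ratios as `joint_cdf` (also the igraph edge
#' `weight`).
#'
#' @param pt a pruned [pair_table()].
#' @return igraph undirected network with graph attribute `phenotype`; an
#'   empty pair table yields an empty network (with a message).
#' @export
build_network <- function(pt) {
  ids <- attr(pt, "dataset_ids")
  phen <- attr(pt, "phenotype")
  if (nrow(pt) == 0L) {
    message("build_network: no retained pairs; returning empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::set_graph_attr(g, "phenotype", phen %||% ""))
  }
  ratios <- as.matrix(pt[, paste0("ratio.", ids), drop = FALSE])
  w <- apply(ratios, 1L, joint_cdf)
  el <- data.frame(from = pt$gene1, to = pt$gene2, stringsAsFactors = FALSE)
  for (id in ids) el[[paste0("cor_", id)]] <- pt[[paste0("cor.", id)]]
  el$joint_cdf <- w
  el$weight <- w
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::set_graph_attr(g, "phenotype", phen %||% "")
}

#' One-call network construction for a phenotype set
#'
#' `pair_table()` then `prune_pairs()` then `build_network()`.
#'
#' @inheritParams pair_table
#' @inheritParams prune_pairs
#' @return igraph co-expression network.
#' @export
coexpression_network <- function(pset, threshold = 0.5) {
  build_network(prune_pairs(pair_table(pset), threshold))
}
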