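#' Single map-equation partition
#'
#' One run of the Infomap (map-equation) community detection heuristic on
#' a weighted network, deterministic for a given seed. Partitions are
#' non-overlapping and two-level.
#'
#' @param net weighted igraph network with positive edge weights.
#' @param seed integer seed controlling the heuristic's randomness.
#' @return A `Partition`: list with `membership` (named integer vector,
#'   one cluster id per node), `seed`, and `codelength` (the map-equation
#'   objective).
#' @export
partition_once <- function(net, seed) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stopf("cannot partition an empty network")
  w <- igraph::E(net)$weight
  if (!is.null(w) && any(w <= 0)) stopf("edge weights must be positive")
  cm <- withr::with_seed(seed, igraph::cluster_infomap(net, e.weights = w))
  structure(list(membership = canonical_membership(igraph::membership(cm)),
                 seed = seed,
                 codelength = cm$codelength),
            class = "Partition")
}

# relabel clusters 1, 2, ... in order of first appearance so that two
# partitions are comparable with identical()
canonical_membership <- function(mem) {
  setNames(match(mem, unique(mem)), names(mem))
}

#' Iterative consensus clustering
#'
#' Runs `runs_per_iter` map-equation partitions (seeds
#' `master_seed + 1, master_seed + 2, ...`), builds the consensus matrix
#' of pairwise co-assignment frequencies, zeroes entries below `tau`, and
#' re-clusters the resulting weighted consensus graph; this repeats until
#' all partitions of an iteration agree, i.e. a complete consensus is
#' reached that further clustering does not change.
#'
#' @param net weighted igraph network.
#' @param runs_per_iter partitions per iteration (>= 2; the study-scale
#'   default is 500).
#' @param tau consensus-matrix threshold in (0, 1); co-assignment
#'   frequencies below `tau` are zeroed.
#' @param max_iter iteration cap; exceeding it is an error that reports
#'   the last agreement fraction.
#' @param master_seed base seed for the derived per-run seeds.
#' @return list with `partition` (the consensus `Partition`) and
#'   `iterations` (number of iterations used).
#' @export
consensus_cluster <- function(net, runs_per_iter = 500L, tau = 0.5,
                              max_iter = 10L, master_seed = 1L) {
  if (runs_per_iter < 2L) stopf("runs_per_iter must be >= 2")
  check_range(tau, 0, 1, "tau")
  if (tau == 0 || tau == 1) stopf("tau must be strictly inside (0, 1)")
  if (igraph::vcount(net) == 0L) stopf("cannot cluster an empty network")
  nodes <- igraph::V(net)$name
  g <- net
  counter <- 0L
  agreement <- NA_real_
  for (iter in seq_len(max_iter)) {
    parts <- vector("list", runs_per_iter)
    for (i in seq_len(runs_per_iter)) {
      counter <- counter + 1L
      parts[[i]] <- partition_once(g, master_seed + counter)
    }
    mems <- lapply(parts, function(p) p$membership[nodes])
    same <- vapply(mems[-1L], identical, NA, mems[[1L]])
    agreement <- (1 + sum(same)) / runs_per_iter
    if (all(same))
      return(list(partition = structure(
        list(membership = mems[[1L]], seed = master_seed,
             codelength = parts[[1L]]$codelength), class = "Partition"),
        iterations = iter))
    # consensus matrix: co-assignment frequency over the runs
    co <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
    for (m in mems) {
      ind <- outer(m, m, "==") * 1
      co <- co + ind
    }
    co <- co / runs_per_iter
    co[co < tau] <- 0
    diag(co) <- 1
    g <- igraph::graph_from_adjacency_matrix(co, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
  }
  stopf("consensus not reached in %d iterations (last agreement %.3f)",
        max_iter, agreement)
}

#' Node-inclusion cleanup against a configuration-model null
#'
#' For each cluster member `v` with degree `k_v`, of which `k_in` edges
#' stay inside the cluster, the null probability of observing at least
#' `k_in` internal neighbours is the hypergeometric tail over edge
#' endpoints: `v`'s `k_v` stubs sample from the `2m - k_v` remaining
#' stubs, of which the other cluster members own `K`. Members whose tail
#' probability exceeds `alpha_node` are dropped; the pass is then applied
#' once more to the pruned cluster.
#'
#' @param net igraph network.
#' @param cluster character vector of member node names.
#' @param alpha_node significance level for keeping a node (default 0.05).
#' @return character vector: the retained members.
#' @export
node_inclusion_cleanup <- function(net, cluster, alpha_node = 0.05) {
  stopifnot(all(cluster %in% igraph::V(net)$name))
  m2 <- 2L * igraph::ecount(net)
  pass <- function(cl) {
    if (length(cl) <= 1L) return(character(0))
    deg <- igraph::degree(net, cl)
    Ktot <- sum(deg)
    keep <- vapply(cl, function(v) {
      nb <- igraph::neighbors(net, v)$name
      k_in <- sum(nb %in% setdiff(cl, v))
      k_v <- deg[[v]]
      K <- Ktot - k_v
      M <- m2 - k_v
      p <- phyper(k_in - 1L, K, M - K, k_v, lower.tail = FALSE)
      p <= alpha_node
    }, NA)
    cl[keep]
  }
  pass(pass(cluster))
}

#' Cluster significance from a degree-preserving null ensemble
#'
#' The observed score is the sum of edge weights internal to the cluster.
#' Each null replicate rewires the network preserving every node's degree
#' and shuffles the edge-weight multiset over the rewired edges; the
#' p-value is `(1 + #\{null >= observed\}) / (n_null + 1)`, so p is never 0.
#'
#' @param net weighted igraph network.
#' @param cluster character vector of member node names (>= 2).
#' @param n_null number of null networks (>= 99).
#' @param seed RNG seed.
#' @return p-value in (0, 1\].
#' @export
cluster_significance <- function(net, cluster, n_null = 199L, seed = 1L) {
  if (length(cluster) < 2L) stopf("cluster must have at least 2 members")
  if (n_null < 99L) stopf("n_null below 99 gives too coarse a p-value")
  stopifnot(all(cluster %in% igraph::V(net)$name))
  score <- function(g) {
    sub <- igraph::induced_subgraph(g, cluster)
    if (igraph::ecount(sub) == 0L) 0 else sum(igraph::E(sub)$weight)
  }
  obs <- score(net)
  w <- igraph::E(net)$weight
  nswap <- max(100L, 10L * igraph::ecount(net))
  null_scores <- withr::with_seed(seed, vapply(seq_len(n_null), function(b) {
    g0 <- igraph::rewire(net, igraph::keeping_degseq(niter = nswap))
    igraph::E(g0)$weight <- sample(w)
    score(g0)
  }, 0))
  (1 + sum(null_scores >= obs)) / (n_null + 1)
}

#' Per-dataset correlation summary of a cluster
#'
#' Mean and standard deviation of the Pearson correlations over all
#' within-cluster gene pairs, separately for each dataset of the
#' phenotype set.
#'
#' @param cluster character vector of gene ids (>= 2).
#' @param pset a [phenotype_set()] containing those genes.
#' @return data.frame with columns `dataset_id`, `mean_cor`, `sd_cor`.
#' @export
summarize_cluster <- function(cluster, pset) {
  if (length(cluster) < 2L) stopf("cluster must have at least 2 members")
  stopifnot(inherits(pset, "PhenotypeSet"))
  rows <- lapply(names(pset$matrices), function(id) {
    v <- pset$matrices[[id]]$values[cluster, , drop = FALSE]
    cc <- cor(t(v))
    r <- cc[upper.tri(cc)]
    data.frame(dataset_id = id, mean_cor = mean(r),
               sd_cor = if (length(r) > 1L) sd(r) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score a partition's clusters: cleanup, significance, summary
#'
#' Applies [node_inclusion_cleanup()] to each cluster of the partition,
#' estimates each cleaned cluster's significance with
#' [cluster_significance()], and (when a phenotype set is supplied)
#' attaches per-dataset correlation summaries. Clusters reduced below 2
#' members by cleanup are dropped.
#'
#' @param net the clustered network.
#' @param partition a `Partition` from [consensus_cluster()] or
#'   [partition_once()].
#' @param n_null,seed passed to [cluster_significance()].
#' @param alpha_node passed to [node_inclusion_cleanup()].
#' @param pset optional [phenotype_set()] for correlation summaries.
#' @return list of `ScoredCluster` objects: `cluster_id`, `genes`,
#'   `p_value`, `summary`.
#' @export
score_clusters <- function(net, partition, n_null = 199L, seed = 1L,
                           alpha_node = 0.05, pset = NULL) {
  mem <- partition$membership
  out <- list()
  for (cid in sort(unique(mem))) {
    genes <- names(mem)[mem == cid]
    genes <- node_inclusion_cleanup(net, genes, alpha_node)
    if (length(genes) < 2L) next
    p <- cluster_significance(net, genes, n_null = n_null, seed = seed + cid)
    smry <- if (!is.null(pset)) summarize_cluster(genes, pset) else NULL
    out[[length(out) + 1L]] <- structure(
      list(cluster_id = sprintf("%s_%d",
                                igraph::graph_attr(net, "phenotype") %||% "C",
                                cid),
           genes = sort(genes), p_value = p, summary = smry),
      class = "ScoredCluster")
  }
  out
}

#' Filter scored clusters by size and significance
#'
#' A cluster is kept only if it has at least `min_size` members AND its
#' significance p-value is below `alpha`; failing either criterion
#' excludes it.
#'
#' @param clusters list of scored clusters.
#' @param min_size minimum member count (default 10).
#' @param alpha significance level (default 0.05); `p >= alpha` excludes.
#' @return the retained sublist.
#' @export
filter_clusters <- function(clusters, min_size = 10L, alpha = 0.05) {
  Filter(function(cl) length(cl$genes) >= min_size && cl$p_value < alpha,
         clusters)
}
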