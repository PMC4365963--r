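# two disjoint weighted cliques, a standard easy community fixture
two_cliques <- function(k = 5) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k),
                              igraph::make_full_graph(k))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(2 * k))
  igraph::E(g)$weight <- 1
  g
}

test_that("map-equation partitioning separates disconnected cliques", {
  g <- two_cliques()
  p <- partition_once(g, seed = 3)
  expect_equal(length(unique(p$membership)), 2)
  expect_equal(length(unique(p$membership[1:5])), 1)
  expect_equal(length(unique(p$membership[6:10])), 1)
  expect_identical(p$membership, partition_once(g, seed = 3)$membership)
  expect_error(partition_once(igraph::make_empty_graph(0), 1), "empty")
})

test_that("a single-edge network yields a degenerate but valid partition", {
  g <- igraph::make_graph(c("A", "B"), directed = FALSE)
  igraph::E(g)$weight <- 1
  p <- partition_once(g, seed = 1)
  expect_true(length(unique(p$membership)) %in% c(1, 2))
})

test_that("consensus clustering converges immediately on disconnected cliques", {
  g <- two_cliques()
  res <- consensus_cluster(g, runs_per_iter = 10, master_seed = 1)
  expect_equal(res$iterations, 1)
  expect_equal(length(unique(res$partition$membership)), 2)
})

test_that("consensus is idempotent on its own converged output", {
  g <- two_cliques()
  res <- consensus_cluster(g, runs_per_iter = 10, master_seed = 2)
  mem <- res$partition$membership
  # consensus graph of a fully agreed partition: cluster cliques, weight 1
  co <- outer(mem, mem, "==") * 1
  diag(co) <- 0
  cg <- igraph::graph_from_adjacency_matrix(co, mode = "undirected",
                                            weighted = TRUE)
  p2 <- partition_once(cg, seed = 99)
  expect_equal(length(unique(p2$membership)), length(unique(mem)))
  tab <- table(mem[igraph::V(cg)$name], p2$membership)
  expect_true(all(rowSums(tab > 0) == 1))   # one-to-one cluster match
})

test_that("consensus recovers planted modules on a synthetic network", {
  skip_if_not_installed("mclust")
  d <- small_design(n_genes = 120, rho = 0.85, module_size = 30,
                    n_samples = 20, seed = 6, extra_modules = list(
                      module_spec("M2", sprintf("g%04d", 31:60), 0.85),
                      module_spec("M3", sprintf("g%04d", 61:90), 0.85)))
  gen <- generate_datasets(d)
  mats <- lapply(gen$matrices, function(m)
    if (m$platform == "count") log_cpm(m) else m)
  net <- coexpression_network(group_by_phenotype(mats)$LA)
  res <- consensus_cluster(net, runs_per_iter = 50, master_seed = 7)
  mem <- res$partition$membership
  truth <- rep("bg", length(mem)); names(truth) <- names(mem)
  for (m in d$modules) {
    hit <- intersect(names(truth), m$member_genes)
    truth[hit] <- m$module_id
  }
  ari <- mclust::adjustedRandIndex(truth, mem[names(truth)])
  expect_gte(ari, 0.8)
})

test_that("node cleanup matches a brute-force configuration-model tail", {
  fx <- clique_in_background(n_bg = 100, p_bg = 0.02, clique_size = 10,
                             seed = 5)
  g <- fx$graph
  # attach one spurious node to the clique by a single edge
  spur <- "v050"
  if (!igraph::are_adjacent(g, spur, fx$clique[1]))
    g <- igraph::add_edges(g, c(spur, fx$clique[1]),
                           attr = list(weight = 0.7))
  cl <- c(fx$clique, spur)
  kept <- node_inclusion_cleanup(g, cl, alpha_node = 0.05)
  expect_true(all(fx$clique %in% kept))
  expect_false(spur %in% kept)
  # brute-force tail for one clique member agrees with the rule's decision
  v <- fx$clique[2]
  deg <- igraph::degree(g)
  k_v <- deg[[v]]
  k_in <- sum(igraph::neighbors(g, v)$name %in% setdiff(cl, v))
  K <- sum(deg[setdiff(cl, v)])
  M <- 2 * igraph::ecount(g) - k_v
  tail_p <- sum(dhyper(k_in:k_v, K, M - K, k_v))
  expect_lt(tail_p, 0.05)
})

test_that("a weakly attached node is cleaned out of a large cluster", {
  # degree-10 node with no internal edge in a 20-node cluster: tail = 1
  fx <- clique_in_background(n_bg = 300, p_bg = 0.03, clique_size = 20,
                             seed = 9)
  g <- fx$graph
  outsider <- setdiff(igraph::V(g)$name, fx$clique)
  outsider <- outsider[which(igraph::degree(g, outsider) >= 5)][1]
  expect_false(outsider %in%
                 node_inclusion_cleanup(g, c(fx$clique, outsider), 0.05))
})

test_that("cluster significance calibrates against rewired nulls", {
  fx <- clique_in_background(seed = 2)
  p <- cluster_significance(fx$graph, fx$clique, n_null = 199, seed = 1)
  expect_lte(p, 0.05)
  expect_gt(p, 0)
  # the whole (connected) network is never significant: weight conserved
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- letters[1:6]
  igraph::E(g)$weight <- runif(15)
  expect_equal(cluster_significance(g, letters[1:6], n_null = 99, seed = 1), 1)
  expect_error(cluster_significance(fx$graph, fx$clique, n_null = 50), "99")
  expect_error(cluster_significance(fx$graph, fx$clique[1], 199), "2 members")
})

test_that("cluster summaries report per-dataset pair correlations", {
  d <- small_design(n_genes = 150, rho = 0.8, module_size = 10,
                    n_samples = 20, seed = 4)
  gen <- generate_datasets(d)
  mats <- lapply(gen$matrices, function(m)
    if (m$platform == "count") log_cpm(m) else m)
  pset <- group_by_phenotype(mats)$LA
  genes <- d$modules[[1]]$member_genes
  sm <- summarize_cluster(genes, pset)
  expect_identical(sm$dataset_id, c("DS1", "DS2", "DS3"))
  expect_true(all(sm$mean_cor > 0.65 & sm$mean_cor < 0.95))
  # a two-gene cluster has sd 0 and mean equal to the single pair r
  sm2 <- summarize_cluster(genes[1:2], pset)
  expect_true(all(sm2$sd_cor == 0))
  r <- cor(pset$matrices[["DS2"]]$values[genes[1], ],
           pset$matrices[["DS2"]]$values[genes[2], ])
  expect_equal(sm2$mean_cor[sm2$dataset_id == "DS2"], r)
  # uncorrelated background genes have mean near 0
  bg <- setdiff(sprintf("g%04d", 1:150), genes)[1:10]
  expect_lt(abs(mean(summarize_cluster(bg, pset)$mean_cor)), 0.2)
})

test_that("cluster filtering applies the size and significance rules disjunctively", {
  mk <- function(n, p) list(cluster_id = "x", genes = sprintf("g%d", 1:n),
                            p_value = p, summary = NULL)
  kept <- filter_clusters(list(mk(11, 0.04384), mk(9, 0.001), mk(50, 0.05),
                               mk(10, 0.0499)), min_size = 10, alpha = 0.05)
  expect_equal(length(kept), 2)
  expect_setequal(vapply(kept, function(x) length(x$genes), 0L), c(11L, 10L))
})
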