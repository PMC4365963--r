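test_that("pairwise Pearson correlation covers every unordered pair", {
  v <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1),
             g4 = c(1, 3, 2, 5))
  colnames(v) <- paste0("s", 1:4)
  em <- expression_matrix(v, "D", "intensity", "LA")
  pp <- pearson_pairs(em)
  expect_equal(nrow(pp), 4 * 3 / 2)
  r12 <- pp$r[pp$gene1 == "g1" & pp$gene2 == "g2"]
  r13 <- pp$r[pp$gene1 == "g1" & pp$gene2 == "g3"]
  expect_equal(r12, 1)      # identical profiles up to scale
  expect_equal(r13, -1)     # negated profile
  expect_error(pearson_pairs(tiny_matrix(matrix(1:4, 2, 2,
    dimnames = list(c("a", "b"), c("s1", "s2"))), platform = "intensity")),
    "3 samples")
  vz <- rbind(v, gz = c(1, 1, 1, 1))
  expect_warning(ppz <- pearson_pairs(
    expression_matrix(vz, "D", "intensity", "LA")), "zero-variance")
  expect_equal(nrow(ppz), 6)
})

test_that("rank ratios follow the absolute-value, average-tie convention", {
  expect_equal(rank_ratios(c(0.1, 0.5, 0.9)), c(1/3, 2/3, 1))
  expect_equal(rank_ratios(c(0.4, 0.4)), c(0.75, 0.75))
  expect_equal(rank_ratios(c(-0.9, 0.1)), c(1, 0.5))
  # untied ranks sum to N (N + 1) / 2
  withr::with_seed(1, {
    r <- runif(40, -1, 1)
    expect_equal(sum(rank_ratios(r) * 40), 40 * 41 / 2)
  })
  # monotone transform of |r| and permutation-equivariant
  r <- c(0.2, -0.8, 0.5, -0.1)
  rr <- rank_ratios(r)
  expect_identical(order(rr), order(abs(r)))
  perm <- c(3, 1, 4, 2)
  expect_equal(rank_ratios(r[perm]), rr[perm])
})

test_that("the joint CDF reproduces its exact identities", {
  expect_equal(joint_cdf(0.3), 0.3)
  expect_equal(joint_cdf(c(0.5, 0.5)), 0.25)
  expect_equal(joint_cdf(c(0.2, 0.5, 0.9)), 0.29, tolerance = 1e-12)
  for (n in 1:6) expect_equal(joint_cdf(rep(1, n)), 1)
  expect_equal(joint_cdf(c(0, 0.5, 0.8)), 0)
  # unsorted input is sorted internally
  expect_equal(joint_cdf(c(0.9, 0.2, 0.5)), joint_cdf(c(0.2, 0.5, 0.9)))
  expect_error(joint_cdf(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(joint_cdf(numeric(0)), "1 to 10")
})

test_that("the joint CDF is non-decreasing in every coordinate", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(2:4, 1)
      r <- sort(runif(n))
      base <- joint_cdf(r)
      i <- sample(n, 1)
      r2 <- r; r2[i] <- min(1, r2[i] + runif(1, 0, 1 - r2[i]))
      expect_gte(joint_cdf(r2) + 1e-12, base)
    }
  })
})

test_that("the joint CDF agrees with a Monte-Carlo oracle", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      n <- sample(2:4, 1)
      r <- runif(n)
      mc <- mc_joint_cdf(r, draws = 2e5)
      expect_lt(abs(joint_cdf(r) - mc$p), 4 * mc$se + 1e-9)
    }
  })
})

test_that("pruning requires every dataset to exceed the threshold", {
  pt <- data.frame(gene1 = c("a", "a", "b"), gene2 = c("b", "c", "c"),
                   cor.D1 = c(0.6, 0.6, 0.9), ratio.D1 = c(2, 1, 3) / 3,
                   cor.D2 = c(0.7, 0.7, -0.2), ratio.D2 = c(1, 2, 3) / 3,
                   cor.D3 = c(0.55, 0.50, 0.8), ratio.D3 = c(2, 1, 3) / 3)
  attr(pt, "phenotype") <- "LA"
  attr(pt, "dataset_ids") <- c("D1", "D2", "D3")
  class(pt) <- c("PairTable", class(pt))
  kept <- prune_pairs(pt, 0.5)
  expect_equal(nrow(kept), 1)               # (0.6, 0.7, 0.55) only
  expect_identical(kept$gene2[1], "b")
  # exactly at threshold is trimmed; conflicting sign is trimmed
  expect_false(any(kept$cor.D3 <= 0.5))
  # edge count is monotone non-increasing in the threshold
  counts <- vapply(c(0, 0.5, 0.6, 0.9), function(th)
    nrow(prune_pairs(pt, th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("network construction attaches per-dataset correlations and weights", {
  pt <- data.frame(gene1 = c("a", "a", "b"), gene2 = c("b", "c", "d"),
                   cor.D1 = c(0.8, 0.7, 0.9), ratio.D1 = c(2, 1, 3) / 3,
                   cor.D2 = c(0.9, 0.6, 0.7), ratio.D2 = c(3, 1, 2) / 3)
  attr(pt, "phenotype") <- "HA"
  attr(pt, "dataset_ids") <- c("D1", "D2")
  net <- build_network(pt)
  expect_lte(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 3)
  expect_equal(igraph::graph_attr(net, "phenotype"), "HA")
  expect_setequal(c("cor_D1", "cor_D2", "joint_cdf", "weight"),
                  igraph::edge_attr_names(net))
  # edge weight equals the joint cdf of the pair's sorted ratios
  e1 <- igraph::E(net)[1]
  expect_equal(igraph::E(net)$joint_cdf[1], joint_cdf(c(2/3, 3/3)))

  empty <- pt[0, ]
  attr(empty, "phenotype") <- "HA"
  attr(empty, "dataset_ids") <- c("D1", "D2")
  expect_message(net0 <- build_network(empty), "empty")
  expect_equal(igraph::vcount(net0), 0)
})

test_that("a planted module's genes dominate the network nodes", {
  d <- small_design(n_genes = 100, rho = 0.9, module_size = 20,
                    n_samples = 10, seed = 2)
  gen <- generate_datasets(d)
  mats <- lapply(gen$matrices, function(m)
    if (m$platform == "count") log_cpm(m) else m)
  net <- coexpression_network(group_by_phenotype(mats)$LA)
  hits <- intersect(igraph::V(net)$name, d$modules[[1]]$member_genes)
  expect_gte(length(hits), 18)
})
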