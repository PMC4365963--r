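# a small DAG with two branches under one root, mixed edge types
sim_dag <- function() {
  ontology_graph(
    terms = data.frame(id = c("R", "A", "B", "A1", "A2", "B1"),
                       name = c("root", "a", "b", "a1", "a2", "b1"),
                       namespace = "biological_process"),
    edges = data.frame(child = c("A", "B", "A1", "A2", "B1"),
                       parent = c("R", "R", "A", "A", "B"),
                       relation = c("is_a", "is_a", "is_a", "part_of", "is_a")))
}

test_that("hypergeometric overlap matches closed forms and enumeration", {
  a <- sprintf("g%02d", 1:10); b <- sprintf("g%02d", 11:20)
  h0 <- hypergeom_overlap(a, b, 100)
  expect_equal(h0$overlap, 0)
  expect_equal(h0$p_value, 1)
  h1 <- hypergeom_overlap(a, a, 100)
  expect_equal(h1$overlap, 10)
  expect_equal(h1$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  b5 <- c(a[1:5], sprintf("g%02d", 21:25))
  h5 <- hypergeom_overlap(a, b5, 100)
  expect_equal(h5$overlap, 5)
  expect_equal(h5$p_value, enum_overlap_tail(10, 10, 5, 100),
               tolerance = 1e-12)
  expect_error(hypergeom_overlap(sprintf("g%03d", 1:50), b, 20), "universe")
})

test_that("hypergeometric overlap matches enumeration on random instances", {
  withr::with_seed(41, {
    for (i in 1:25) {
      N <- sample(20:60, 1)
      universe <- sprintf("u%03d", 1:N)
      a <- sample(universe, sample(3:12, 1))
      b <- sample(universe, sample(3:12, 1))
      h <- hypergeom_overlap(a, b, N)
      expect_equal(h$p_value,
                   enum_overlap_tail(length(a), length(b), h$overlap, N),
                   tolerance = 1e-12)
    }
  })
})

test_that("Wang similarity reproduces hand-computed values", {
  dag <- sim_dag()
  expect_equal(wang_similarity("A", "A", dag), 1)
  # child vs root: (0.8 + 1) / (1.8 + 1)
  expect_equal(wang_similarity("A", "R", dag), 1.8 / 2.8, tolerance = 1e-12)
  # part_of child vs its parent: S-values of A2 are (1, 0.6, 0.48),
  # of A are (1, 0.8); shared ancestors {A, R} give (0.6+1)+(0.48+0.8)
  expect_equal(wang_similarity("A2", "A", dag), 2.88 / 3.88,
               tolerance = 1e-12)
  # disjoint branches share only the root: positive but weaker than siblings
  cross <- wang_similarity("A1", "B1", dag)
  sib <- wang_similarity("A1", "A2", dag)
  expect_gt(cross, 0)
  expect_lt(cross, sib)
  expect_error(wang_similarity("ZZ", "A", dag), "unknown term")
})

test_that("Wang similarity is symmetric, bounded and matches a recursive oracle", {
  genes <- sprintf("g%04d", 1:20)
  fx <- generate_ontology_fixture(25, 4, genes, seed = 13)
  dag <- fx$ontology
  ids <- dag$terms$id
  withr::with_seed(14, {
    for (i in 1:20) {
      ab <- sample(ids, 2)
      s <- wang_similarity(ab[1], ab[2], dag)
      expect_equal(s, wang_similarity(ab[2], ab[1], dag), tolerance = 1e-12)
      expect_gte(s, 0); expect_lte(s, 1)
      expect_equal(s, wang_oracle(ab[1], ab[2], dag), tolerance = 1e-12)
    }
  })
  expect_equal(wang_similarity(ids[5], ids[5], dag), 1)
})

test_that("best-match averaging follows its defining formula", {
  expect_equal(bma_combine(matrix(0.4, 1, 1)), 0.4)
  expect_equal(bma_combine(matrix(c(0.2, 0.8), 2, 1)), 0.6)
  m <- matrix(c(0.1, 0.7, 0.3, 0.9, 0.2, 0.5), 2, 3)
  expect_equal(bma_combine(m), bma_combine(t(m)), tolerance = 1e-12)
  # identical term sets give 1 via a unit-diagonal similarity matrix
  dag <- sim_dag()
  ts <- c("A1", "B1")
  expect_equal(bma_combine(wang_sim_matrix(ts, ts, dag)), 1)
  expect_error(bma_combine(matrix(numeric(0), 0, 0)), "empty")
})

test_that("the similarity null sample is reproducible with honest spread", {
  dag <- generate_ontology_fixture(30, 4, sprintf("g%04d", 1:10),
                                   seed = 15)$ontology
  pool <- dag$terms$id
  n1 <- sample_null(pool, sizes = c(3, 5, 8), n = 200, seed = 5, dag = dag)
  n2 <- sample_null(pool, sizes = c(3, 5, 8), n = 200, seed = 5, dag = dag)
  expect_identical(n1$values, n2$values)
  expect_true(all(n1$values >= 0 & n1$values <= 1))
  expect_gt(sd(n1$values), 0)
  # degenerate pool: every draw is the single term, similarity 1
  n3 <- sample_null(pool[1], sizes = 1, n = 100, seed = 1, dag = dag)
  expect_true(all(n3$values == 1))
  expect_error(sample_null(pool, sizes = 99, n = 100, seed = 1, dag = dag),
               "pool")
})

test_that("empirical p-values count strict exceedances", {
  null <- structure(list(values = c(0.1, 0.2, 0.3, 0.4), n = 4, seed = 1),
                    class = "NullSimSample")
  expect_equal(empirical_pvalue(0.9, null), 0)
  expect_equal(empirical_pvalue(0.05, null), 1)
  expect_equal(empirical_pvalue(0.25, null), 0.5)
  expect_equal(empirical_pvalue(0.3, null), 0.25)  # ties don't count
})

test_that("similarity graphs keep only significant edges", {
  mk <- function(id, genes) list(cluster_id = id, genes = genes,
                                 p_value = 0.01, summary = NULL)
  shared <- sprintf("g%03d", 1:15)
  la <- list(mk("LA_1", shared), mk("LA_2", sprintf("g%03d", 30:45)))
  ha <- list(mk("HA_1", shared), mk("HA_2", sprintf("g%03d", 60:75)))
  sg <- similarity_graphs(la, ha, universe_size = 500)
  expect_equal(igraph::vcount(sg$physical), 4)
  hit <- igraph::as_edgelist(sg$physical)
  expect_true(any(hit[, 1] == "LA_1" & hit[, 2] == "HA_1"))
  e <- igraph::E(sg$physical)[igraph::V(sg$physical)["LA_1"] %--%
                              igraph::V(sg$physical)["HA_1"]]
  expect_equal(e$label, 15)    # identical cluster: overlap = its size
  # disjoint pairs stay unlinked
  expect_false(igraph::are_adjacent(sg$physical, "LA_2", "HA_2"))
  # with no clusters at all, graphs are empty
  sg0 <- similarity_graphs(list(), list(), universe_size = 500)
  expect_equal(igraph::ecount(sg0$physical), 0)
  expect_equal(igraph::ecount(sg0$functional), 0)
})

test_that("functional similarity links clusters with matching enriched terms", {
  dag <- sim_dag()
  enr <- function(terms) {
    out <- data.frame(term_id = terms, name = terms,
                      n_genes = 6, p_value = 0.001,
                      genes = "", stringsAsFactors = FALSE)
    class(out) <- c("EnrichmentResult", class(out))
    out
  }
  mk <- function(id) list(cluster_id = id, genes = sprintf("%s_g%d", id, 1:12),
                          p_value = 0.01, summary = NULL)
  la <- list(mk("LA_1")); ha <- list(mk("HA_1"), mk("HA_2"))
  enrichments <- list(LA_1 = enr(c("A1", "A2")), HA_1 = enr(c("A1", "A2")),
                      HA_2 = enr("B1"))
  null <- sample_null(dag$terms$id, sizes = c(1, 2), n = 400, seed = 3,
                      dag = dag)
  sg <- similarity_graphs(la, ha, enrichments = enrichments,
                          universe_size = 100, dag = dag, null = null)
  # the near-identical term sets are linked; the cross-branch pair is not
  expect_true(igraph::are_adjacent(sg$functional, "LA_1", "HA_1"))
  ft <- sg$functional_table
  expect_true(all(c("LA_1", "HA_1", "HA_2") %in%
                    c(ft$cluster_a, ft$cluster_b)))
  # within-phenotype pairs are tested too (HA_1 vs HA_2 present)
  expect_true(any(ft$cluster_a == "HA_1" & ft$cluster_b == "HA_2"))
})
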