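# Shared fixtures and independent oracles for the test suite.

# small expression matrix with explicit values
tiny_matrix <- function(vals = matrix(1:6, 3, 2,
                                      dimnames = list(c("gA", "gB", "gC"),
                                                      c("s1", "s2"))),
                        id = "D1", platform = "count", phenotype = "LA") {
  expression_matrix(vals, id, platform, phenotype)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# three-dataset phenotype-pair design used across modules
small_design <- function(n_genes = 100L, rho = 0.9, module_size = 20L,
                         n_samples = 15L, seed = 1L,
                         present = "both", extra_modules = list()) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  synthetic_design(
    n_genes = n_genes,
    datasets = data.frame(dataset_id = c("DS1", "DS2", "DS3"),
                          platform = c("count", "intensity", "intensity"),
                          n_la = n_samples, n_ha = n_samples,
                          stringsAsFactors = FALSE),
    modules = c(list(module_spec("M1", genes[seq_len(module_size)], rho,
                                 present)),
                extra_modules),
    seed = seed)
}

# mean within-module pairwise correlation of an expression matrix
module_mean_cor <- function(em, genes) {
  cc <- cor(t(em$values[genes, , drop = FALSE]))
  mean(cc[upper.tri(cc)])
}

# --- independent oracles -------------------------------------------------

# Monte-Carlo estimate of P(U_(i) <= r_i for all i) with a pmin/pmax
# sorting network (n <= 4), avoiding any use of joint_cdf()
mc_joint_cdf <- function(r, draws = 1e6) {
  n <- length(r)
  u <- matrix(runif(draws * n), draws, n)
  s <- switch(as.character(n),
    "1" = u,
    "2" = {
      cbind(pmin(u[, 1], u[, 2]), pmax(u[, 1], u[, 2]))
    },
    "3" = {
      lo <- pmin(u[, 1], pmin(u[, 2], u[, 3]))
      hi <- pmax(u[, 1], pmax(u[, 2], u[, 3]))
      cbind(lo, u[, 1] + u[, 2] + u[, 3] - lo - hi, hi)
    },
    "4" = {
      a <- pmin(u[, 1], u[, 2]); b <- pmax(u[, 1], u[, 2])
      c_ <- pmin(u[, 3], u[, 4]); d <- pmax(u[, 3], u[, 4])
      lo <- pmin(a, c_); hi <- pmax(b, d)
      m1 <- pmax(a, c_); m2 <- pmin(b, d)
      cbind(lo, pmin(m1, m2), pmax(m1, m2), hi)
    },
    stop("mc oracle supports n <= 4"))
  r_sorted <- sort(r)
  ok <- rep(TRUE, draws)
  for (i in seq_len(n)) ok <- ok & (s[, i] <= r_sorted[i])
  p <- mean(ok)
  list(p = p, se = sqrt(p * (1 - p) / draws))
}

# brute-force one-sided over-representation p by enumerating all 2x2
# tables with the observed margins
enum_fisher_tail <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; n <- a + c
  ks <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= a])
}

# brute-force hypergeometric overlap tail
enum_overlap_tail <- function(sa, sb, k, universe) {
  ks <- max(0, sa + sb - universe):min(sa, sb)
  probs <- choose(sa, ks) * choose(universe - sa, sb - ks) /
    choose(universe, sb)
  sum(probs[ks >= k])
}

# independent recursive (memoised) Wang S-value implementation
wang_oracle_svalues <- function(term, dag, w_is_a = 0.8, w_part_of = 0.6) {
  wts <- c(is_a = w_is_a, part_of = w_part_of)
  closure <- term_ancestors(dag, term)
  memo <- new.env(parent = emptyenv())
  s_of <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    val <- if (t == term) 1 else {
      kids <- dag$edges[dag$edges$parent == t & dag$edges$child %in% closure, ]
      if (nrow(kids) == 0L) 0 else
        max(vapply(seq_len(nrow(kids)),
                   function(i) wts[[kids$relation[i]]] * s_of(kids$child[i]),
                   0))
    }
    memo[[t]] <- val
    val
  }
  setNames(vapply(closure, s_of, 0), closure)
}

wang_oracle <- function(a, b, dag, w_is_a = 0.8, w_part_of = 0.6) {
  sa <- wang_oracle_svalues(a, dag, w_is_a, w_part_of)
  sb <- wang_oracle_svalues(b, dag, w_is_a, w_part_of)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) == 0L) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# simple OBO text fixture writer
write_obo_fixture <- function(stanzas, path = tempfile(fileext = ".obo")) {
  writeLines(c("format-version: 1.2", "", stanzas), path)
  path
}

# planted-clique network: ER background plus a weighted clique
clique_in_background <- function(n_bg = 100, p_bg = 0.03, clique_size = 10,
                                 seed = 1) {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n_bg, p_bg)
    igraph::V(g)$name <- sprintf("v%03d", seq_len(n_bg))
    cl <- sprintf("v%03d", seq_len(clique_size))
    for (i in seq_len(clique_size - 1)) for (j in (i + 1):clique_size)
      if (!igraph::are_adjacent(g, cl[i], cl[j]))
        g <- igraph::add_edges(g, c(cl[i], cl[j]))
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.5, 1)
    list(graph = g, clique = cl)
  })
}

# ground-truth vs predicted labels over the full gene universe
recovery_labels <- function(genes, modules, clusters) {
  truth <- setNames(rep("bg", length(genes)), genes)
  for (m in modules) truth[m$member_genes] <- m$module_id
  pred <- setNames(rep("bg", length(genes)), genes)
  for (cl in clusters) pred[intersect(cl$genes, genes)] <- cl$cluster_id
  list(truth = truth, pred = pred)
}
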