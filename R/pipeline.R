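#' Assemble a run configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults
#' used throughout the package: correlation pruning at +0.50, cluster
#' retention at size >= 10 and p < 0.05, enrichment reporting at p < 0.05
#' with >= 5 annotated genes, similarity significance at p < 0.05,
#' 500 partitions per consensus iteration and a 10,000-draw similarity
#' null.
#'
#' @param matrices list of [expression_matrix()] objects (in-memory
#'   input), or `NULL` if `datasets` provides paths.
#' @param datasets optional data.frame with columns `path`, `dataset_id`,
#'   `platform`, `phenotype` for loading from disk.
#' @param probe_maps optional named list (by dataset id) of
#'   [probe_map()] objects for probe collapsing.
#' @param ontology,go_annotations,pathways optional [ontology_graph()],
#'   GO [annotation_table()] and pathway [annotation_table()]; enrichment
#'   and functional similarity are skipped when absent.
#' @param prior_count log-CPM prior count.
#' @param cor_threshold pruning threshold on signed correlation.
#' @param runs_per_iter,tau,max_iter consensus-clustering controls.
#' @param n_null rewiring replicates for cluster significance.
#' @param alpha_node node-inclusion cleanup level.
#' @param min_size,cluster_alpha cluster retention filters.
#' @param enrich_alpha,min_annotated,elim_alpha enrichment controls.
#' @param similarity_alpha similarity significance level.
#' @param n_sim_null draws for the functional-similarity null.
#' @param seed master seed; every stage derives its randomness from it.
#' @param out_dir optional directory; when set, networks, cluster tables
#'   and enrichment tables are written there.
#' @return a `RunConfig` list.
#' @export
run_config <- function(matrices = NULL, datasets = NULL, probe_maps = NULL,
                       ontology = NULL, go_annotations = NULL,
                       pathways = NULL,
                       prior_count = 0.5, cor_threshold = 0.5,
                       runs_per_iter = 500L, tau = 0.5, max_iter = 10L,
                       n_null = 199L, alpha_node = 0.05,
                       min_size = 10L, cluster_alpha = 0.05,
                       enrich_alpha = 0.05, min_annotated = 5L,
                       elim_alpha = 0.01, similarity_alpha = 0.05,
                       n_sim_null = 10000L, seed = 1L, out_dir = NULL) {
  if (is.null(matrices) && is.null(datasets))
    stopf("provide either in-memory matrices or a datasets table")
  for (a in c(cor_threshold, tau))
    check_range(a, 0, 1, "threshold")
  for (a in c(cluster_alpha, enrich_alpha, similarity_alpha, alpha_node,
              elim_alpha))
    check_range(a, 0, 1, "significance level")
  cfg <- list(matrices = matrices, datasets = datasets,
              probe_maps = probe_maps, ontology = ontology,
              go_annotations = go_annotations, pathways = pathways,
              prior_count = prior_count, cor_threshold = cor_threshold,
              runs_per_iter = as.integer(runs_per_iter), tau = tau,
              max_iter = as.integer(max_iter), n_null = as.integer(n_null),
              alpha_node = alpha_node, min_size = as.integer(min_size),
              cluster_alpha = cluster_alpha, enrich_alpha = enrich_alpha,
              min_annotated = as.integer(min_annotated),
              elim_alpha = elim_alpha, similarity_alpha = similarity_alpha,
              n_sim_null = as.integer(n_sim_null), seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Load a run configuration from a YAML file
#'
#' The YAML mirrors the arguments of [run_config()]; datasets are listed
#' under `datasets:` with `path`, `dataset_id`, `platform`, `phenotype`
#' keys, and `ontology`/`go_annotations`/`pathways` may be file paths
#' (OBO and TSV respectively).
#'
#' @param path YAML file path.
#' @return a `RunConfig`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  ds <- do.call(rbind, lapply(y$datasets, function(d)
    data.frame(path = d$path, dataset_id = d$dataset_id,
               platform = d$platform, phenotype = d$phenotype,
               stringsAsFactors = FALSE)))
  y$datasets <- ds
  if (!is.null(y$ontology) && is.character(y$ontology))
    y$ontology <- read_obo(y$ontology)
  if (!is.null(y$go_annotations) && is.character(y$go_annotations))
    y$go_annotations <- read_annotations(y$go_annotations,
                                         namespace = "biological_process")
  if (!is.null(y$pathways) && is.character(y$pathways))
    y$pathways <- read_annotations(y$pathways, namespace = "pathway")
  do.call(run_config, y)
}

# load, log-CPM transform and probe-collapse all configured matrices
prepare_matrices <- function(config) {
  mats <- config$matrices
  if (is.null(mats)) {
    mats <- lapply(seq_len(nrow(config$datasets)), function(i) {
      d <- config$datasets[i, ]
      read_expression(d$path, d$dataset_id, d$platform, d$phenotype)
    })
  }
  lapply(mats, function(m) {
    pm <- config$probe_maps[[m$dataset_id]]
    if (!is.null(pm)) m <- collapse_probes(m, pm)
    if (m$platform == "count") m <- log_cpm(m, config$prior_count)
    m
  })
}

phenotype_seed <- function(config, phenotype) {
  config$seed + (match(phenotype, PHENOTYPES) - 1L) * 100000L
}

#' Run the analysis for one phenotype group
#'
#' Preprocess (log-CPM, probe collapse, common-gene intersection) ->
#' cross-dataset network construction -> consensus clustering ->
#' significance scoring and filtering -> enrichment (when annotations are
#' configured). A manifest records the seed and the counts at every
#' stage.
#'
#' @param config a [run_config()].
#' @param phenotype `"LA"` or `"HA"`.
#' @param matrices optional pre-prepared matrix list (internal reuse).
#' @return list with `phenotype`, `network`, `partition`, `iterations`,
#'   `clusters_all`, `clusters` (significant only), `go`, `pathway`
#'   (per-cluster enrichment tables), `background`, `manifest`.
#' @export
run_phenotype <- function(config, phenotype, matrices = NULL) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  mats <- matrices %||% prepare_matrices(config)
  sets <- group_by_phenotype(mats)
  pset <- sets[[phenotype]]
  if (is.null(pset)) stopf("no matrices for phenotype %s", phenotype)
  background <- gene_ids(pset$matrices[[1L]])
  seed0 <- phenotype_seed(config, phenotype)

  pt <- pair_table(pset)
  kept <- prune_pairs(pt, config$cor_threshold)
  net <- build_network(kept)
  manifest <- list(phenotype = phenotype, seed = seed0,
                   n_common_genes = length(background),
                   pairs_computed = nrow(pt), pairs_retained = nrow(kept),
                   n_nodes = igraph::vcount(net),
                   n_edges = igraph::ecount(net))
  if (igraph::vcount(net) == 0L) {
    manifest <- c(manifest, list(iterations = 0L, n_clusters = 0L,
                                 n_significant = 0L))
    return(list(phenotype = phenotype, network = net, partition = NULL,
                iterations = 0L, clusters_all = list(), clusters = list(),
                go = list(), pathway = list(), background = background,
                manifest = manifest))
  }
  cons <- consensus_cluster(net, runs_per_iter = config$runs_per_iter,
                            tau = config$tau, max_iter = config$max_iter,
                            master_seed = seed0)
  scored <- score_clusters(net, cons$partition, n_null = config$n_null,
                           seed = seed0, alpha_node = config$alpha_node,
                           pset = pset)
  sig <- filter_clusters(scored, config$min_size, config$cluster_alpha)
  manifest <- c(manifest, list(iterations = cons$iterations,
                               n_clusters = length(scored),
                               n_significant = length(sig)))
  go <- list(); pw <- list()
  for (cl in sig) {
    if (!is.null(config$ontology) && !is.null(config$go_annotations))
      go[[cl$cluster_id]] <- go_enrich(
        cl$genes, background, config$ontology, config$go_annotations,
        elim_alpha = config$elim_alpha, p_cutoff = config$enrich_alpha,
        min_genes = config$min_annotated)
    if (!is.null(config$pathways))
      pw[[cl$cluster_id]] <- pathway_enrich(
        cl$genes, background, config$pathways,
        p_cutoff = config$enrich_alpha, min_genes = config$min_annotated)
  }
  res <- list(phenotype = phenotype, network = net,
              partition = cons$partition, iterations = cons$iterations,
              clusters_all = scored, clusters = sig, go = go, pathway = pw,
              background = background, manifest = manifest)
  if (!is.null(config$out_dir)) write_phenotype_outputs(res, config$out_dir)
  res
}

write_phenotype_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ph <- res$phenotype
  if (igraph::vcount(res$network) > 0L)
    write_network(res$network, file.path(out_dir, paste0(ph, "_network.graphml")))
  write_clusters(res$clusters, file.path(out_dir, paste0(ph, "_clusters.tsv")))
  for (cid in names(res$go))
    write_enrichment(res$go[[cid]],
                     file.path(out_dir, paste0(cid, "_go.tsv")))
  for (cid in names(res$pathway))
    write_enrichment(res$pathway[[cid]],
                     file.path(out_dir, paste0(cid, "_kegg.tsv")))
  invisible(NULL)
}

#' Run the full two-phenotype analysis plus cluster similarity
#'
#' [run_phenotype()] for LA and HA on a shared preprocessed gene
#' universe, then physical (hypergeometric) and functional (Wang + BMA
#' with empirical null) similarity between the significant clusters.
#'
#' @param config a [run_config()].
#' @return list with `LA`, `HA` (each a [run_phenotype()] result),
#'   `similarity` (see [similarity_graphs()]; `NULL` when there are no
#'   clusters to compare) and `manifest`.
#' @export
run_full <- function(config) {
  mats <- prepare_matrices(config)
  la <- run_phenotype(config, "LA", matrices = mats)
  ha <- run_phenotype(config, "HA", matrices = mats)
  sim <- NULL
  if (length(la$clusters) + length(ha$clusters) > 0L) {
    enr <- c(la$go, ha$go)
    null <- NULL
    sizes <- vapply(enr, nrow, 0L)
    if (!is.null(config$ontology) && !is.null(config$go_annotations) &&
        any(sizes > 0L)) {
      ann <- propagate_annotations(config$go_annotations, config$ontology)
      pool <- unique(ann$term_id[ann$gene_id %in% la$background])
      null <- sample_null(pool, sizes[sizes > 0L],
                          n = config$n_sim_null,
                          seed = config$seed + 900000L,
                          dag = config$ontology)
    }
    sim <- similarity_graphs(la$clusters, ha$clusters, enrichments = enr,
                             universe_size = length(la$background),
                             dag = config$ontology, null = null,
                             alpha = config$similarity_alpha)
  }
  list(LA = la, HA = ha, similarity = sim,
       manifest = list(LA = la$manifest, HA = ha$manifest))
}

#' Leave-one-dataset-out sanity check
#'
#' Reruns one phenotype's analysis without the named dataset and compares
#' the reduced run's significant clusters to the full run's via the
#' hypergeometric overlap test, mirroring the reduced-versus-full cluster
#' comparison used to probe how strongly a single dataset drives the
#' clustering.
#'
#' @param config a [run_config()].
#' @param excluded_dataset_id dataset id to leave out.
#' @param phenotype phenotype to compare (default `"LA"`).
#' @return list with `full`, `reduced` (the two [run_phenotype()]
#'   results) and `comparison` (data.frame: cluster ids, sizes, common
#'   gene count, p-value, one row per reduced-by-full cluster pair).
#' @export
sanity_check <- function(config, excluded_dataset_id, phenotype = "LA") {
  mats <- prepare_matrices(config)
  ids <- vapply(mats, `[[`, "", "dataset_id")
  if (!excluded_dataset_id %in% ids)
    stopf("dataset '%s' is not part of the configuration", excluded_dataset_id)
  reduced_mats <- mats[ids != excluded_dataset_id]
  ph_count <- table(vapply(reduced_mats, `[[`, "", "phenotype"))
  if (any(ph_count < 2L))
    stopf("excluding '%s' leaves fewer than 2 datasets in a phenotype",
          excluded_dataset_id)
  full <- run_phenotype(config, phenotype, matrices = mats)
  reduced <- run_phenotype(config, phenotype, matrices = reduced_mats)
  universe <- length(full$background)
  comp <- data.frame()
  for (a in reduced$clusters) for (b in full$clusters) {
    h <- hypergeom_overlap(a$genes, b$genes, universe)
    comp <- rbind(comp, data.frame(
      reduced_cluster = a$cluster_id, full_cluster = b$cluster_id,
      size_reduced = length(a$genes), size_full = length(b$genes),
      common = h$overlap, p_value = h$p_value, stringsAsFactors = FALSE))
  }
  list(full = full, reduced = reduced, comparison = comp)
}
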