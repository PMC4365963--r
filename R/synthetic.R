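#' Describe a planted co-expression module
#'
#' A module is a set of genes that share a per-sample latent factor in the
#' phenotype group(s) where the module is active, so that each pair of
#' member genes has expected Pearson correlation close to
#' `within_correlation` in every dataset of that phenotype.
#'
#' @param module_id short label.
#' @param member_genes character vector of gene ids.
#' @param within_correlation target pairwise correlation, strictly in (0, 1).
#' @param present_in_phenotype `"both"`, `"LA"` or `"HA"`; a
#'   phenotype-specific module contributes its latent factor only to that
#'   phenotype's samples (member genes look like background elsewhere).
#' @return A `ModuleSpec` object.
#' @export
module_spec <- function(module_id, member_genes, within_correlation,
                        present_in_phenotype = c("both", "LA", "HA")) {
  present_in_phenotype <- match.arg(present_in_phenotype)
  if (!(within_correlation > 0 && within_correlation < 1))
    stopf("within_correlation must be strictly between 0 and 1")
  if (anyDuplicated(member_genes)) stopf("duplicate member genes")
  structure(list(module_id = module_id,
                 member_genes = as.character(member_genes),
                 within_correlation = within_correlation,
                 present_in_phenotype = present_in_phenotype),
            class = "ModuleSpec")
}

#' Describe a multi-dataset synthetic study design
#'
#' The defaults emulate the study layout this package targets: three liver
#' expression datasets per phenotype group — one sequencing-style count
#' dataset and two array-style intensity datasets — each measured on a
#' low-androstenone (LA) and a high-androstenone (HA) sample group of 29
#' animals.
#'
#' @param n_genes total number of genes.
#' @param datasets data.frame with columns `dataset_id`, `platform`
#'   (`count`/`intensity`), `n_la`, `n_ha` (samples per phenotype, each at
#'   least 3).
#' @param modules list of [module_spec()] objects with disjoint member
#'   sets; member gene ids must exist among the `n_genes` generated ids
#'   (`g0001`, `g0002`, ...).
#' @param nb_dispersion negative-binomial dispersion for count datasets
#'   (variance = mu + dispersion * mu^2).
#' @param intensity_noise_sd standard deviation of intensity noise.
#' @param seed master seed; each dataset consumes its own derived stream
#'   (`seed + dataset index`) so adding a dataset does not perturb the
#'   ones before it.
#' @return A `SyntheticDesign` object.
#' @export
synthetic_design <- function(n_genes = 300L,
                             datasets = data.frame(
                               dataset_id = c("DS1", "DS2", "DS3"),
                               platform = c("count", "intensity", "intensity"),
                               n_la = 29L, n_ha = 29L,
                               stringsAsFactors = FALSE),
                             modules = list(),
                             nb_dispersion = 0.1,
                             intensity_noise_sd = 1,
                             seed = 1L) {
  stopifnot(is.data.frame(datasets),
            all(c("dataset_id", "platform", "n_la", "n_ha") %in% names(datasets)))
  if (any(datasets$n_la < 3L) || any(datasets$n_ha < 3L))
    stopf("every dataset needs at least 3 samples per phenotype")
  if (!all(datasets$platform %in% PLATFORMS)) stopf("unknown platform")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (intensity_noise_sd <= 0) stopf("intensity_noise_sd must be > 0")
  genes <- sprintf("g%04d", seq_len(n_genes))
  all_members <- unlist(lapply(modules, `[[`, "member_genes"))
  if (anyDuplicated(all_members))
    stopf("module gene sets must be disjoint")
  if (!all(all_members %in% genes))
    stopf("module genes outside the generated gene universe")
  structure(list(n_genes = as.integer(n_genes), genes = genes,
                 datasets = datasets, modules = modules,
                 nb_dispersion = nb_dispersion,
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed)),
            class = "SyntheticDesign")
}

#' Generate synthetic multi-dataset expression data
#'
#' For each dataset and phenotype, module member genes load on a shared
#' standard-normal latent factor per sample. Intensity datasets use
#' `value = baseline + sd * (sqrt(rho) * latent + sqrt(1 - rho) * noise)`,
#' which gives pairwise correlation exactly `rho` in expectation. Count
#' datasets use a log-linear negative-binomial model,
#' `mu = exp(b + beta * latent)`, with `beta` calibrated by a delta-method
#' rule (`beta = sqrt(rho / (1 - rho) * (1 / mu0 + dispersion))`) so that
#' member-pair correlation of log-transformed counts is approximately
#' `rho`. Background genes are independent.
#'
#' @param design a [synthetic_design()].
#' @return A list with `matrices` (one [expression_matrix()] per dataset
#'   per phenotype, count datasets count-valued) and `modules` (the ground
#'   truth [module_spec()] list).
#' @export
generate_datasets <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  genes <- design$genes
  mats <- list()
  for (i in seq_len(nrow(design$datasets))) {
    ds <- design$datasets[i, ]
    block <- withr::with_seed(design$seed + i, {
      # gene baselines, fixed within dataset
      base <- if (ds$platform == "count") rnorm(length(genes), 5, 0.7)
              else rnorm(length(genes), 8, 1)
      lapply(PHENOTYPES, function(ph) {
        n <- if (ph == "LA") ds$n_la else ds$n_ha
        x <- matrix(0, length(genes), n,
                    dimnames = list(genes, sprintf("%s_%s_s%02d",
                                                   ds$dataset_id, ph, 1:n)))
        # latent factor per active module
        latent <- lapply(design$modules, function(m)
          if (m$present_in_phenotype %in% c("both", ph)) rnorm(n) else NULL)
        if (ds$platform == "intensity") {
          eps <- matrix(rnorm(length(genes) * n), length(genes), n)
          x <- base + design$intensity_noise_sd * eps
          for (k in seq_along(design$modules)) {
            if (is.null(latent[[k]])) next
            m <- design$modules[[k]]
            rho <- m$within_correlation
            gi <- match(m$member_genes, genes)
            x[gi, ] <- base[gi] + design$intensity_noise_sd *
              (sqrt(rho) * matrix(latent[[k]], length(gi), n, byrow = TRUE) +
               sqrt(1 - rho) * eps[gi, , drop = FALSE])
          }
        } else {
          logmu <- matrix(base, length(genes), n)
          for (k in seq_along(design$modules)) {
            if (is.null(latent[[k]])) next
            m <- design$modules[[k]]
            rho <- m$within_correlation
            gi <- match(m$member_genes, genes)
            beta <- sqrt(rho / (1 - rho) *
                         (1 / exp(base[gi]) + design$nb_dispersion))
            logmu[gi, ] <- base[gi] +
              outer(beta, latent[[k]])
          }
          x[] <- rnbinom(length(logmu), mu = exp(logmu),
                         size = 1 / design$nb_dispersion)
        }
        dimnames(x) <- list(genes, sprintf("%s_%s_s%02d", ds$dataset_id, ph, 1:n))
        expression_matrix(x, ds$dataset_id, ds$platform, ph)
      })
    })
    names(block) <- PHENOTYPES
    mats[[ds$dataset_id]] <- block
  }
  list(matrices = unlist(mats, recursive = FALSE),
       modules = design$modules)
}

#' Generate a toy ontology plus gene annotations
#'
#' Builds a rooted random DAG of `n_terms` biological-process terms with
#' typed `is_a`/`part_of` edges and annotates `genes` to random terms.
#' One designated term (`T_planted`) annotates exactly `planted_genes`, so
#' enrichment tests have a known positive. Annotations are returned
#' up-propagated (true-path rule).
#'
#' @param n_terms number of terms (>= 3).
#' @param max_depth maximum depth of the DAG below the root.
#' @param genes character vector of gene ids to annotate.
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param planted_genes genes annotated to the planted term (default: the
#'   first `min(10, length(genes))` genes).
#' @param p_part_of probability a parent link is `part_of` rather than
#'   `is_a`.
#' @return list with `ontology` ([ontology_graph()]), `annotations`
#'   (propagated [annotation_table()]) and `planted_term` (its id).
#' @export
generate_ontology_fixture <- function(n_terms, max_depth = 3L, genes,
                                      seed = 1L, planted_genes = NULL,
                                      p_part_of = 0.2) {
  if (n_terms < 3L) stopf("need at least 3 terms")
  planted_genes <- planted_genes %||% genes[seq_len(min(10L, length(genes)))]
  withr::with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_terms))
    depth <- c(0L, rep(NA_integer_, n_terms - 1L))
    ch <- pa <- rel <- character(0)
    for (k in 2:n_terms) {
      cand <- which(!is.na(depth) & depth < max_depth)
      p1 <- sample(cand, 1L)
      depth[k] <- depth[p1] + 1L
      ch <- c(ch, ids[k]); pa <- c(pa, ids[p1])
      rel <- c(rel, if (runif(1) < p_part_of) "part_of" else "is_a")
      # occasional second parent keeps it a genuine DAG, not a tree
      cand2 <- setdiff(which(!is.na(depth) & depth < depth[k]), p1)
      if (length(cand2) > 0L && runif(1) < 0.25) {
        p2 <- if (length(cand2) == 1L) cand2 else sample(cand2, 1L)
        ch <- c(ch, ids[k]); pa <- c(pa, ids[p2])
        rel <- c(rel, if (runif(1) < p_part_of) "part_of" else "is_a")
      }
    }
    onto <- ontology_graph(
      terms = data.frame(id = ids, name = paste("term", ids),
                         namespace = "biological_process",
                         stringsAsFactors = FALSE),
      edges = data.frame(child = ch, parent = pa, relation = rel,
                         stringsAsFactors = FALSE))
    # planted term: a leaf-most term annotating exactly the planted genes
    planted <- ids[which.max(depth)]
    g <- rep(character(0), 0); t <- character(0)
    for (gn in genes) {
      k <- sample(seq_len(min(3L, n_terms - 1L)), 1L)
      t0 <- sample(ids[-1L], k)
      g <- c(g, rep(gn, k)); t <- c(t, t0)
    }
    ann <- annotation_table(c(g, planted_genes),
                            c(t, rep(planted, length(planted_genes))),
                            namespace = "biological_process")
    list(ontology = onto,
         annotations = propagate_annotations(ann, onto),
         planted_term = planted)
  })
}
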