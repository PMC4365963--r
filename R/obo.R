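#' Construct an ontology graph
#'
#' Directed acyclic graph over ontology terms with typed child-to-parent
#' edges (`is_a`, `part_of`), as consumed by enrichment testing and Wang
#' semantic similarity. Obsolete terms are never part of the graph;
#' secondary (`alt_id`) identifiers are aliased to their primary term.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @param alt named character vector mapping alternate ids to primary ids
#'   (may be empty).
#' @return An object of class `OntologyGraph`.
#' @export
ontology_graph <- function(terms, edges,
                           alt = setNames(character(0), character(0))) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id)) stopf("duplicated term ids")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
    unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
    if (length(unknown) > 0L)
      stopf("edge references unknown term(s): %s",
            paste(head(unknown, 3L), collapse = ", "))
    if (!all(edges$relation %in% c("is_a", "part_of")))
      stopf("edge relations must be is_a or part_of")
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges) > 0L) edges[, c("child", "parent")] else
      data.frame(child = character(0), parent = character(0)),
    directed = TRUE, vertices = terms$id)
  if (!igraph::is_dag(g)) stopf("ontology contains a cycle")
  structure(list(terms = terms, edges = edges, alt = alt, graph = g),
            class = "OntologyGraph")
}

#' @export
print.OntologyGraph <- function(x, ...) {
  cat(sprintf("OntologyGraph: %d terms, %d edges (%d is_a, %d part_of)\n",
              nrow(x$terms), nrow(x$edges),
              sum(x$edges$relation == "is_a"),
              sum(x$edges$relation == "part_of")))
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Consumes `[Term]` stanzas only. `is_a` and `relationship: part_of` lines
#' become typed edges; any other relationship type is ignored with a
#' warning. Terms flagged `is_obsolete: true` are dropped; `alt_id` lines
#' are recorded as aliases of the primary id.
#'
#' @param path path to an OBO 1.2 text file.
#' @return An [ontology_graph()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  ends <- c(starts[-1L] - 1L, length(lines))
  idx <- match(term_starts, starts)

  ids <- character(0); nms <- character(0); ns <- character(0)
  ch <- character(0); pa <- character(0); rel <- character(0)
  alt_from <- character(0); alt_to <- character(0)
  skipped_rel <- character(0)

  strip <- function(x) sub("\\s*!.*$", "", x)
  for (k in seq_along(term_starts)) {
    block <- lines[(term_starts[k] + 1L):ends[idx[k]]]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v)) trimws(strip(v)) else character(0)
    }
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    id <- get1("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    ids <- c(ids, id)
    nms <- c(nms, get1("name")[1L] %||% id)
    ns <- c(ns, get1("namespace")[1L] %||% NA_character_)
    for (p in get1("is_a")) { ch <- c(ch, id); pa <- c(pa, p); rel <- c(rel, "is_a") }
    for (r in get1("relationship")) {
      parts <- strsplit(trimws(r), "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of") {
        ch <- c(ch, id); pa <- c(pa, parts[2L]); rel <- c(rel, "part_of")
      } else {
        skipped_rel <- c(skipped_rel, parts[1L])
      }
    }
    for (a in get1("alt_id")) { alt_from <- c(alt_from, a); alt_to <- c(alt_to, id) }
  }
  if (length(skipped_rel) > 0L)
    warnf("ignored %d relationship line(s) of unhandled type(s): %s",
          length(skipped_rel), paste(unique(skipped_rel), collapse = ", "))
  ns[is.na(ns)] <- "unknown"
  keep <- pa %in% ids   # edges to obsolete/missing parents are dropped
  ontology_graph(
    terms = data.frame(id = ids, name = nms, namespace = ns,
                       stringsAsFactors = FALSE),
    edges = data.frame(child = ch[keep], parent = pa[keep],
                       relation = rel[keep], stringsAsFactors = FALSE),
    alt = setNames(alt_to, alt_from))
}

#' Resolve possibly-alternate term ids to primary ids
#' @param onto an [ontology_graph()].
#' @param ids character vector of term ids.
#' @return character vector of primary ids (unknown ids left unchanged).
#' @export
resolve_terms <- function(onto, ids) {
  hit <- ids %in% names(onto$alt)
  ids[hit] <- unname(onto$alt[ids[hit]])
  ids
}

#' Ancestors of a term (self included)
#' @inheritParams resolve_terms
#' @param id a single primary term id.
#' @return character vector of term ids: `id` and all its ancestors.
#' @export
term_ancestors <- function(onto, id) {
  if (!id %in% onto$terms$id) stopf("unknown term '%s'", id)
  names(igraph::subcomponent(onto$graph, id, mode = "out"))
}

#' Term depths (longest path from a root)
#'
#' Depth 0 for roots (terms with no parents); every other term's depth is
#' one more than the maximum depth of its parents. Used to order terms for
#' the `elim` enrichment pass (deepest first).
#'
#' @inheritParams resolve_terms
#' @return named integer vector of depths.
#' @export
term_depths <- function(onto) {
  g <- onto$graph
  ord <- igraph::topo_sort(g, mode = "in")  # parents before children
  depth <- setNames(integer(igraph::vcount(g)), igraph::V(g)$name)
  for (v in ord$name) {
    pars <- igraph::neighbors(g, v, mode = "out")$name
    depth[v] <- if (length(pars) == 0L) 0L else max(depth[pars]) + 1L
  }
  depth
}

#' Build or validate a gene annotation table
#'
#' @param gene_id,term_id character vectors of equal length: each row
#'   annotates one gene with one term.
#' @param namespace optional tag recorded on the table (e.g.
#'   `"biological_process"` or `"pathway"`).
#' @return data.frame of class `AnnotationTable` with columns `gene_id`,
#'   `term_id`.
#' @export
annotation_table <- function(gene_id, term_id, namespace = NA_character_) {
  if (length(gene_id) != length(term_id)) stopf("column length mismatch")
  df <- unique(data.frame(gene_id = as.character(gene_id),
                          term_id = as.character(term_id),
                          stringsAsFactors = FALSE))
  attr(df, "namespace") <- namespace
  class(df) <- c("AnnotationTable", class(df))
  df
}

#' Read a gene-to-term annotation TSV (columns gene_id, term_id)
#' @param path TSV path.
#' @inheritParams annotation_table
#' @export
read_annotations <- function(path, namespace = NA_character_) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  annotation_table(df[[1L]], df[[2L]], namespace = namespace)
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term. Alternate ids are resolved before propagation; terms absent
#' from the ontology are dropped with a warning.
#'
#' @param ann an [annotation_table()].
#' @param onto an [ontology_graph()].
#' @return A propagated `AnnotationTable`.
#' @export
propagate_annotations <- function(ann, onto) {
  tid <- resolve_terms(onto, ann$term_id)
  known <- tid %in% onto$terms$id
  if (!all(known))
    warnf("dropping %d annotation(s) to terms absent from the ontology",
          sum(!known))
  ann <- data.frame(gene_id = ann$gene_id[known], term_id = tid[known],
                    stringsAsFactors = FALSE)
  anc <- lapply(unique(ann$term_id), function(t) term_ancestors(onto, t))
  names(anc) <- unique(ann$term_id)
  out <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    a <- anc[[ann$term_id[i]]]
    data.frame(gene_id = ann$gene_id[i], term_id = a,
               stringsAsFactors = FALSE)
  }))
  annotation_table(out$gene_id, out$term_id,
                   namespace = attr(ann, "namespace"))
}
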