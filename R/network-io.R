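#' Export a co-expression network to GraphML or XGMML
#'
#' Every edge must carry one `cor_<dataset_id>` attribute per contributing
#' dataset plus the `joint_cdf` weight; exporting a network with missing
#' edge attributes is an error. Numeric attributes are serialised at full
#' double precision, so a write/read round trip reproduces them to at
#' least 12 significant digits. XGMML output follows the Cytoscape
#' convention of per-edge `<att>` elements.
#'
#' @param net an igraph co-expression network (see [build_network()]).
#' @param path output file path.
#' @param dialect `"graphml"` (default) or `"xgmml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("graphml", "xgmml")) {
  dialect <- match.arg(dialect)
  stopifnot(igraph::is_igraph(net))
  eattr <- igraph::edge_attr_names(net)
  num_attrs <- sort(grep("^cor_", eattr, value = TRUE))
  if (igraph::ecount(net) > 0L) {
    if (length(num_attrs) == 0L || !"joint_cdf" %in% eattr)
      stopf("network edges must carry cor_<dataset> attributes and joint_cdf")
    num_attrs <- c(num_attrs, "joint_cdf")
    for (a in num_attrs)
      if (anyNA(igraph::edge_attr(net, a)))
        stopf("edge attribute '%s' has missing values", a)
  } else {
    num_attrs <- c(num_attrs, intersect("joint_cdf", eattr))
  }
  phen <- igraph::graph_attr(net, "phenotype") %||% ""
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = FALSE)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- if (dialect == "graphml") {
    keydefs <- c(
      '  <key id="k_name" for="node" attr.name="name" attr.type="string"/>',
      '  <key id="k_phen" for="graph" attr.name="phenotype" attr.type="string"/>',
      vapply(num_attrs, function(a) sprintf(
        '  <key id="k_%s" for="edge" attr.name="%s" attr.type="double"/>',
        a, a), ""))
    nd <- sprintf('    <node id="n%d"><data key="k_name">%s</data></node>',
                  seq_along(nodes) - 1L, esc(nodes))
    ed <- if (nrow(el) > 0L) {
      attdata <- sapply(num_attrs, function(a)
        sprintf('<data key="k_%s">%s</data>', a,
                fmt_num(igraph::edge_attr(net, a))))
      attdata <- apply(matrix(attdata, nrow = nrow(el)), 1L, paste0, collapse = "")
      sprintf('    <edge source="n%d" target="n%d">%s</edge>',
              el[, 1L] - 1L, el[, 2L] - 1L, attdata)
    } else character(0)
    c('<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      keydefs,
      '  <graph edgedefault="undirected">',
      sprintf('    <data key="k_phen">%s</data>', esc(phen)),
      nd, ed,
      '  </graph>', '</graphml>')
  } else {
    nd <- sprintf('  <node id="%d" label="%s"/>',
                  seq_along(nodes), esc(nodes))
    ed <- if (nrow(el) > 0L) {
      attdata <- sapply(num_attrs, function(a)
        sprintf('<att name="%s" type="real" value="%s"/>', a,
                fmt_num(igraph::edge_attr(net, a))))
      attdata <- apply(matrix(attdata, nrow = nrow(el)), 1L, paste0, collapse = "")
      sprintf('  <edge source="%d" target="%d" label="%s (pp) %s">%s</edge>',
              el[, 1L], el[, 2L], esc(nodes[el[, 1L]]), esc(nodes[el[, 2L]]),
              attdata)
    } else character(0)
    c('<?xml version="1.0" encoding="UTF-8"?>',
      sprintf('<graph label="%s" directed="0" xmlns="http://www.cs.rpi.edu/XGMML">',
              esc(phen)),
      sprintf('  <att name="phenotype" type="string" value="%s"/>', esc(phen)),
      nd, ed, '</graph>')
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path GraphML or XGMML file.
#' @param dialect `"graphml"` or `"xgmml"`.
#' @return An igraph network with node names, numeric edge attributes and
#'   the `phenotype` graph attribute restored.
#' @export
read_network <- function(path, dialect = c("graphml", "xgmml")) {
  dialect <- match.arg(dialect)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (dialect == "graphml") {
    keys <- xml2::xml_find_all(doc, ".//key")
    kmap <- setNames(xml2::xml_attr(keys, "attr.name"),
                     xml2::xml_attr(keys, "id"))
    ktype <- setNames(xml2::xml_attr(keys, "attr.type"),
                      xml2::xml_attr(keys, "id"))
    nds <- xml2::xml_find_all(doc, ".//node")
    nid <- xml2::xml_attr(nds, "id")
    nname <- xml2::xml_text(xml2::xml_find_first(nds, "./data"))
    eds <- xml2::xml_find_all(doc, ".//edge")
    src <- match(xml2::xml_attr(eds, "source"), nid)
    tgt <- match(xml2::xml_attr(eds, "target"), nid)
    g <- igraph::make_empty_graph(n = length(nid), directed = FALSE)
    igraph::V(g)$name <- nname
    if (length(eds) > 0L)
      g <- igraph::add_edges(g, rbind(src, tgt))
    # edge attributes, one pass per declared edge key
    for (kid in names(kmap)) {
      if (!grepl("^k_(cor_|joint_cdf)", kid)) next
      vals <- xml2::xml_text(
        xml2::xml_find_first(eds, sprintf("./data[@key='%s']", kid)))
      if (length(eds) > 0L)
        g <- igraph::set_edge_attr(g, kmap[[kid]],
          value = if (ktype[[kid]] == "double") as.numeric(vals) else vals)
    }
    phen_node <- xml2::xml_find_first(doc, ".//graph/data[@key='k_phen']")
    if (!inherits(phen_node, "xml_missing"))
      g <- igraph::set_graph_attr(g, "phenotype", xml2::xml_text(phen_node))
  } else {
    nds <- xml2::xml_find_all(doc, "./node")
    nid <- xml2::xml_attr(nds, "id")
    nname <- xml2::xml_attr(nds, "label")
    eds <- xml2::xml_find_all(doc, "./edge")
    g <- igraph::make_empty_graph(n = length(nid), directed = FALSE)
    igraph::V(g)$name <- nname
    if (length(eds) > 0L) {
      src <- match(xml2::xml_attr(eds, "source"), nid)
      tgt <- match(xml2::xml_attr(eds, "target"), nid)
      g <- igraph::add_edges(g, rbind(src, tgt))
      atts <- xml2::xml_find_all(eds[[1L]], "./att")
      for (a in xml2::xml_attr(atts, "name")) {
        vals <- as.numeric(xml2::xml_attr(
          xml2::xml_find_first(eds, sprintf("./att[@name='%s']", a)), "value"))
        g <- igraph::set_edge_attr(g, a, value = vals)
      }
    }
    phen <- xml2::xml_attr(
      xml2::xml_find_first(doc, "./att[@name='phenotype']"), "value")
    if (!is.na(phen)) g <- igraph::set_graph_attr(g, "phenotype", phen)
  }
  if (igraph::ecount(g) > 0L && "joint_cdf" %in% igraph::edge_attr_names(g))
    igraph::E(g)$weight <- igraph::E(g)$joint_cdf
  g
}

#' Write cluster membership as TSV (cluster_id, gene_id, p_value)
#' @param clusters a list of scored clusters (see [score_clusters()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id, gene_id = cl$genes,
               p_value = cl$p_value, stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(cluster_id = character(0), gene_id = character(0),
                       p_value = numeric(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
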