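#' Write a module collection as XGMML
#'
#' One `<graph>` element per module under a common root, each with its node
#' set (node attributes: `seed` flag, semicolon-joined `metabolites`) and
#' induced edges (edge attribute `confidence`).
#'
#' @param modules list of [network_module()]s.
#' @param path output file.
#' @export
write_xgmml <- function(modules, path) {
  doc <- xml2::xml_new_root("xgmml_collection",
                            xmlns = "http://www.cs.rpi.edu/XGMML")
  for (m in modules) {
    gr <- xml2::xml_add_child(doc, "graph", label = m$network_id,
                              directed = "0")
    if (isTRUE(m$cap_exempt))
      xml2::xml_set_attr(gr, "cap_exempt", "1")
    if (length(m$merged_from))
      xml2::xml_set_attr(gr, "merged_from",
                         paste(m$merged_from, collapse = ";"))
    for (v in m$nodes) {
      nd <- xml2::xml_add_child(gr, "node", id = v, label = v)
      xml2::xml_add_child(nd, "att", name = "seed", type = "boolean",
                          value = tolower(as.character(v %in% m$seeds)))
    }
    if (length(m$linked_metabolites))
      xml2::xml_add_child(gr, "att", name = "metabolites", type = "string",
                          value = paste(m$linked_metabolites, collapse = ";"))
    if (nrow(m$edges)) {
      for (i in seq_len(nrow(m$edges))) {
        ed <- xml2::xml_add_child(gr, "edge", source = m$edges$from[i],
                                  target = m$edges$to[i])
        xml2::xml_add_child(ed, "att", name = "confidence", type = "real",
                            value = format(m$edges$confidence[i],
                                           digits = 15))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a module collection from XGMML
#'
#' Inverse of [write_xgmml()].
#'
#' @param path XGMML file written by [write_xgmml()].
#' @return list of [network_module()]s.
#' @export
read_xgmml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "x")
  graphs <- xml2::xml_find_all(doc, ".//x:graph", ns)
  lapply(graphs, function(gr) {
    nodes <- xml2::xml_find_all(gr, "./x:node", ns)
    ids <- xml2::xml_attr(nodes, "id")
    seed_flag <- vapply(nodes, function(nd) {
      att <- xml2::xml_find_first(nd, "./x:att[@name='seed']", ns)
      identical(xml2::xml_attr(att, "value"), "true")
    }, logical(1))
    edges <- xml2::xml_find_all(gr, "./x:edge", ns)
    edf <- data.frame(
      from = xml2::xml_attr(edges, "source"),
      to = xml2::xml_attr(edges, "target"),
      confidence = vapply(edges, function(ed) {
        att <- xml2::xml_find_first(ed, "./x:att[@name='confidence']", ns)
        as.numeric(xml2::xml_attr(att, "value"))
      }, numeric(1)),
      stringsAsFactors = FALSE)
    met_att <- xml2::xml_find_first(gr, "./x:att[@name='metabolites']", ns)
    mets <- if (!inherits(met_att, "xml_missing"))
      strsplit(xml2::xml_attr(met_att, "value"), ";", fixed = TRUE)[[1]]
    else character(0)
    mf <- xml2::xml_attr(gr, "merged_from")
    network_module(
      network_id = xml2::xml_attr(gr, "label"),
      nodes = ids, edges = edf, seeds = ids[seed_flag],
      linked_metabolites = mets,
      merged_from = if (!is.na(mf)) strsplit(mf, ";", fixed = TRUE)[[1]]
      else character(0),
      cap_exempt = identical(xml2::xml_attr(gr, "cap_exempt"), "1"))
  })
}

#' Export a module collection as GraphML or edge-list TSV
#'
#' @param m a [network_module()].
#' @param path output file.
#' @export
write_module_graphml <- function(m, path) {
  g <- igraph::graph_from_data_frame(
    m$edges, directed = FALSE,
    vertices = data.frame(name = m$nodes,
                          seed = m$nodes %in% m$seeds,
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_module_graphml
#' @export
write_module_edges <- function(m, path) {
  utils::write.table(m$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
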