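#' Read a pathway from the JSON dialect
#'
#' The JSON dialect is a lightweight, self-contained encoding of a pathway
#' topology, convenient for fixtures and for exchanging graphs without KGML:
#'
#' ```json
#' {
#'   "pathway_id": "toy",
#'   "nodes": [{"id": "A", "kind": "single", "genes": ["g1"]}, ...],
#'   "edges": [{"from": "A", "to": "B", "sign": "activation"}, ...]
#' }
#' ```
#'
#' `kind` is one of `single`, `alternatives`, `complex`; `sign` is
#' `activation` or `inhibition`. A graph read from JSON is equivalent to one
#' built by [parse_kgml()] from the corresponding KGML.
#'
#' @param x Path to a JSON file, or a JSON string.
#' @return A [pathway_graph].
#' @export
read_pathway_json <- function(x) {
  doc <- tryCatch(jsonlite::fromJSON(x, simplifyDataFrame = FALSE,
                                     simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed pathway JSON: ", conditionMessage(e),
                         call. = FALSE))
  for (field in c("pathway_id", "nodes")) {
    if (is.null(doc[[field]]))
      stop("pathway JSON: missing required field '$", field, "'")
  }
  if (length(doc$nodes) == 0L)
    stop("pathway JSON: '$nodes' is empty")
  nodes <- list()
  for (i in seq_along(doc$nodes)) {
    nd <- doc$nodes[[i]]
    for (field in c("id", "kind", "genes")) {
      if (is.null(nd[[field]]))
        stop("pathway JSON: missing field '$nodes[", i, "]$", field, "'")
    }
    nodes[[as.character(nd$id)]] <-
      list(kind = as.character(nd$kind),
           genes = unlist(nd$genes, use.names = FALSE))
  }
  edges <- data.frame(from = character(), to = character(),
                      sign = character(), stringsAsFactors = FALSE)
  if (length(doc$edges)) {
    rows <- lapply(seq_along(doc$edges), function(i) {
      ed <- doc$edges[[i]]
      for (field in c("from", "to", "sign")) {
        if (is.null(ed[[field]]))
          stop("pathway JSON: missing field '$edges[", i, "]$", field, "'")
      }
      data.frame(from = as.character(ed$from), to = as.character(ed$to),
                 sign = as.character(ed$sign), stringsAsFactors = FALSE)
    })
    edges <- do.call(rbind, rows)
  }
  pathway_graph(as.character(doc$pathway_id), nodes, edges)
}

#' Write a pathway graph to the JSON dialect
#'
#' @param graph A [pathway_graph].
#' @param path Output file; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @seealso [read_pathway_json()] for the schema.
#' @export
write_pathway_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  doc <- list(
    pathway_id = graph$pathway_id,
    nodes = lapply(names(graph$nodes), function(id)
      list(id = id, kind = graph$nodes[[id]]$kind,
           genes = as.list(graph$nodes[[id]]$genes))),
    edges = lapply(seq_len(nrow(graph$edges)), function(i)
      list(from = graph$edges$from[i], to = graph$edges$to[i],
           sign = graph$edges$sign[i]))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Export a pathway graph as GraphML
#'
#' Writes the signed graph in GraphML with node attributes `kind` and
#' `genes` (comma-separated) and edge attribute `sign`, readable by generic
#' network tools (igraph, Cytoscape, yEd).
#'
#' @param graph A [pathway_graph].
#' @param path Output file; if `NULL`, the GraphML text is returned.
#' @return `path` invisibly, or the GraphML string when `path` is `NULL`.
#' @export
write_graphml <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (key in list(c("d_kind", "node", "kind"),
                   c("d_genes", "node", "genes"),
                   c("d_sign", "edge", "sign"))) {
    xml2::xml_add_child(doc, "key", id = key[1], `for` = key[2],
                        attr.name = key[3], attr.type = "string")
  }
  g <- xml2::xml_add_child(doc, "graph", id = graph$pathway_id,
                           edgedefault = "directed")
  for (id in names(graph$nodes)) {
    n <- xml2::xml_add_child(g, "node", id = id)
    xml2::xml_add_child(n, "data", graph$nodes[[id]]$kind, key = "d_kind")
    xml2::xml_add_child(n, "data", paste(graph$nodes[[id]]$genes,
                                         collapse = ","), key = "d_genes")
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- xml2::xml_add_child(g, "edge",
                             source = graph$edges$from[i],
                             target = graph$edges$to[i])
    xml2::xml_add_child(e, "data", graph$edges$sign[i], key = "d_sign")
  }
  if (is.null(path)) return(as.character(doc))
  xml2::write_xml(doc, path)
  invisible(path)
}
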