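#' Signed directed pathway graph
#'
#' A `pathway_graph` represents one signaling pathway as a signed directed
#' graph. Nodes are proteins or protein groups: a node holds one gene
#' (`kind = "single"`), several redundant alternative genes
#' (`kind = "alternatives"`), or the members of a protein complex that must
#' all be present simultaneously (`kind = "complex"`). Edges carry a sign,
#' either `"activation"` or `"inhibition"`.
#'
#' @param pathway_id Character scalar identifying the pathway.
#' @param nodes Named list; each element a list with fields `kind` (one of
#'   `"single"`, `"alternatives"`, `"complex"`) and `genes` (non-empty
#'   character vector). Names are the node ids.
#' @param edges Data frame with character columns `from`, `to`, `sign`
#'   (`"activation"` or `"inhibition"`).
#' @return An object of class `pathway_graph`: a list with components
#'   `pathway_id`, `nodes`, `edges`.
#' @examples
#' g <- pathway_graph(
#'   "toy",
#'   nodes = list(A = node_spec("single", "g1"), B = node_spec("single", "g2")),
#'   edges = data.frame(from = "A", to = "B", sign = "activation")
#' )
#' print(g)
#' @export
pathway_graph <- function(pathway_id, nodes, edges) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L)
  if (length(nodes) == 0L)
    stop("pathway '", pathway_id, "': node list is empty")
  ids <- names(nodes)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("pathway '", pathway_id, "': all nodes must be named")
  if (anyDuplicated(ids))
    stop("pathway '", pathway_id, "': duplicated node ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (i in seq_along(nodes)) {
    nodes[[i]] <- validate_node_spec(nodes[[i]], ids[i])
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.character(edges$sign)
  bad <- setdiff(unique(c(edges$from, edges$to)), ids)
  if (length(bad))
    stop("pathway '", pathway_id, "': edges reference unknown nodes: ",
         paste(bad, collapse = ", "))
  if (!all(edges$sign %in% c("activation", "inhibition")))
    stop("pathway '", pathway_id, "': edge sign must be activation/inhibition")
  if (any(edges$from == edges$to))
    stop("pathway '", pathway_id, "': self-edges are not allowed")
  edges <- unique(edges)
  # a duplicated source->target pair with conflicting signs resolves to
  # inhibition (an inhibitory mechanism overrides, cf. classify_relation)
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    sign <- tapply(edges$sign, key, function(s)
      if (any(s == "inhibition")) "inhibition" else "activation")
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$sign <- as.character(sign[paste(edges$from, edges$to, sep = "\r")])
  }
  rownames(edges) <- NULL
  structure(list(pathway_id = pathway_id, nodes = nodes, edges = edges),
            class = "pathway_graph")
}

#' Construct a node specification
#'
#' @param kind `"single"`, `"alternatives"` or `"complex"`.
#' @param genes Character vector of gene identifiers.
#' @return A list with fields `kind` and `genes`.
#' @export
node_spec <- function(kind, genes) {
  validate_node_spec(list(kind = kind, genes = genes), "<unnamed>")
}

validate_node_spec <- function(node, id) {
  if (!is.list(node) || !all(c("kind", "genes") %in% names(node)))
    stop("node '", id, "': must have fields kind and genes")
  kind <- match.arg(node$kind, c("single", "alternatives", "complex"))
  genes <- unique(as.character(node$genes))
  if (length(genes) == 0L || anyNA(genes) || any(genes == ""))
    stop("node '", id, "': gene list must be non-empty")
  if (kind == "single" && length(genes) != 1L)
    stop("node '", id, "': kind 'single' requires exactly one gene")
  if (kind != "single" && length(genes) < 2L)
    stop("node '", id, "': kind '", kind, "' requires at least two genes")
  list(kind = kind, genes = genes)
}

#' @export
print.pathway_graph <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, "", "kind")
  cat("<pathway_graph> ", x$pathway_id, "\n", sep = "")
  cat("  nodes: ", length(x$nodes),
      " (", sum(kinds == "single"), " single, ",
      sum(kinds == "alternatives"), " alternatives, ",
      sum(kinds == "complex"), " complex)\n", sep = "")
  cat("  edges: ", nrow(x$edges),
      " (", sum(x$edges$sign == "inhibition"), " inhibitions)\n", sep = "")
  invisible(x)
}

#' All genes covered by a pathway graph
#'
#' @param graph A `pathway_graph`.
#' @return Character vector of distinct gene identifiers.
#' @export
pathway_genes <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  unique(unlist(lapply(graph$nodes, `[[`, "genes"), use.names = FALSE))
}

# adjacency helpers used by circuits and propagation -------------------------

out_edges <- function(graph, node) {
  graph$edges[graph$edges$from == node, , drop = FALSE]
}

in_edges <- function(graph, node) {
  graph$edges[graph$edges$to == node, , drop = FALSE]
}

edge_sign <- function(graph, from, to) {
  s <- graph$edges$sign[graph$edges$from == from & graph$edges$to == to]
  if (length(s) == 0L)
    stop("no edge ", from, " -> ", to, " in pathway '", graph$pathway_id, "'")
  # if KGML duplicated the relation with conflicting subtypes the inhibition
  # reading wins, matching classify_relation()
  if (any(s == "inhibition")) "inhibition" else "activation"
}
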