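#' Identify signal input and output nodes
#'
#' A signal input node (stimulus receptor) is a node with no incoming
#' interactions; a signal output node (effector) is a node with no outgoing
#' interactions. Isolated nodes (degree zero) belong to neither set: they
#' can neither receive nor forward a signal.
#'
#' @param graph A [pathway_graph].
#' @return A list with character vectors `inputs` and `outputs`.
#' @examples
#' g <- pathway_graph("chain",
#'   nodes = list(A = node_spec("single", "g1"),
#'                B = node_spec("single", "g2"),
#'                C = node_spec("single", "g3")),
#'   edges = data.frame(from = c("A", "B"), to = c("B", "C"),
#'                      sign = "activation"))
#' find_io_nodes(g)  # inputs "A", outputs "C"
#' @export
find_io_nodes <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ids <- names(graph$nodes)
  indeg <- table(factor(graph$edges$to, levels = ids))
  outdeg <- table(factor(graph$edges$from, levels = ids))
  isolated <- indeg == 0L & outdeg == 0L
  list(inputs = ids[indeg == 0L & !isolated],
       outputs = ids[outdeg == 0L & !isolated])
}

#' Enumerate stimulus-to-effector circuits
#'
#' A circuit connects one signal input node to one signal output node and
#' comprises every loop-free linear path (simple directed path) between
#' them. Paths are discovered by exhaustive depth-first enumeration of all
#' simple paths; (input, output) pairs with no connecting path yield no
#' circuit. A circuit whose path count exceeds `max_paths` is truncated at
#' the cap and flagged.
#'
#' @param graph A [pathway_graph].
#' @param max_paths Cap on the number of linear paths retained per circuit.
#' @return A list of `circuit` objects, each a list with fields
#'   `circuit_id`, `pathway_id`, `input`, `output`, `paths` (list of node-id
#'   vectors), `truncated`.
#' @export
enumerate_circuits <- function(graph, max_paths = 10000L) {
  stopifnot(inherits(graph, "pathway_graph"), max_paths >= 1L)
  io <- find_io_nodes(graph)
  if (length(io$inputs) == 0L || length(io$outputs) == 0L) {
    warning("pathway '", graph$pathway_id,
            "' has no input or no output nodes; no circuits", call. = FALSE)
    return(list())
  }
  adj <- split(graph$edges$to, factor(graph$edges$from,
                                      levels = names(graph$nodes)))
  circuits <- list()
  for (inp in io$inputs) {
    found <- all_simple_paths_to(adj, inp, io$outputs, max_paths)
    for (out in io$outputs) {
      paths <- found[[out]]
      if (length(paths) == 0L) next
      circuits[[length(circuits) + 1L]] <- structure(
        list(circuit_id = paste(inp, out, sep = "->"),
             pathway_id = graph$pathway_id,
             input = inp, output = out,
             paths = paths,
             truncated = isTRUE(attr(found, "truncated")[[out]])),
        class = "circuit")
    }
  }
  if (any(vapply(circuits, `[[`, TRUE, "truncated")))
    warning("pathway '", graph$pathway_id, "': some circuits hit the ",
            max_paths, "-path cap and were truncated", call. = FALSE)
  circuits
}

# iterative DFS enumerating all simple paths from `start` to each node in
# `targets`; returns list target -> list of paths, with a "truncated"
# attribute marking targets whose enumeration hit the cap
all_simple_paths_to <- function(adj, start, targets, max_paths) {
  res <- stats::setNames(rep(list(list()), length(targets)), targets)
  truncated <- stats::setNames(rep(list(FALSE), length(targets)), targets)
  # stack of (path to extend); explicit to avoid deep recursion on big maps
  stack <- list(start)
  while (length(stack)) {
    path <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    tip <- path[length(path)]
    if (tip %in% targets && length(path) > 1L) {
      if (length(res[[tip]]) < max_paths) {
        res[[tip]][[length(res[[tip]]) + 1L]] <- path
      } else {
        truncated[[tip]] <- TRUE
      }
      # an output node has out-degree 0, nothing to extend
    }
    for (nxt in adj[[tip]]) {
      if (!(nxt %in% path)) stack[[length(stack) + 1L]] <- c(path, nxt)
    }
  }
  attr(res, "truncated") <- truncated
  res
}

#' @export
print.circuit <- function(x, ...) {
  cat("<circuit> ", x$circuit_id, " [", x$pathway_id, "]: ",
      length(x$paths), " linear path(s)",
      if (x$truncated) " (truncated)", "\n", sep = "")
  invisible(x)
}

#' Remove circuits that touch a directed cycle
#'
#' Circuits containing loops cannot be modeled by the linear-path union and
#' are discarded: a circuit is removed when any node on any of its paths
#' lies on a directed cycle of the pathway graph.
#'
#' @param circuits List of circuits from [enumerate_circuits()].
#' @param graph The [pathway_graph] the circuits came from.
#' @return A list with `kept` (circuit list) and `removed_count`.
#' @export
remove_looped_circuits <- function(circuits, graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  cyc <- nodes_on_cycles(graph)
  on_cycle <- vapply(circuits, function(circ)
    any(unlist(circ$paths, use.names = FALSE) %in% cyc), TRUE)
  list(kept = circuits[!on_cycle], removed_count = sum(on_cycle))
}

# nodes lying on at least one directed cycle: a node is on a cycle iff it
# can reach itself through at least one edge
nodes_on_cycles <- function(graph) {
  ids <- names(graph$nodes)
  adj <- split(graph$edges$to, factor(graph$edges$from, levels = ids))
  on_cycle <- character(0)
  for (v in ids) {
    # BFS from successors of v
    seen <- character(0)
    frontier <- adj[[v]]
    hit <- FALSE
    while (length(frontier) && !hit) {
      if (v %in% frontier) { hit <- TRUE; break }
      seen <- c(seen, frontier)
      frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                          seen)
    }
    if (hit) on_cycle <- c(on_cycle, v)
  }
  on_cycle
}

#' Enumerate, filter and summarise circuits for a set of pathways
#'
#' Convenience wrapper running [enumerate_circuits()] and
#' [remove_looped_circuits()] over several pathways.
#'
#' @param graphs A [pathway_graph] or list of them.
#' @param max_paths Per-circuit linear-path cap.
#' @return An object of class `circuit_set`: list with `circuits` (flat
#'   list over all pathways), `graphs` (the input graphs, named by pathway
#'   id) and `removed` (named integer vector of removed loop-circuit counts
#'   per pathway).
#' @export
pathway_circuits <- function(graphs, max_paths = 10000L) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  all <- list()
  removed <- integer(0)
  for (g in graphs) {
    circ <- enumerate_circuits(g, max_paths)
    flt <- remove_looped_circuits(circ, g)
    all <- c(all, flt$kept)
    removed[g$pathway_id] <- flt$removed_count
  }
  names(graphs) <- vapply(graphs, `[[`, "", "pathway_id")
  structure(list(circuits = all, graphs = graphs, removed = removed),
            class = "circuit_set")
}

#' @export
print.circuit_set <- function(x, ...) {
  cat("<circuit_set> ", length(x$circuits), " circuit(s) across ",
      length(x$removed), " pathway(s); ", sum(x$removed),
      " removed for loops\n", sep = "")
  invisible(x)
}

#' Tabulate a circuit set
#'
#' @param x A `circuit_set`.
#' @param ... Unused.
#' @return Data frame with one row per circuit: `circuit_id`, `pathway_id`,
#'   `input`, `output`, `n_paths`, `truncated`.
#' @export
as.data.frame.circuit_set <- function(x, ...) {
  do.call(rbind, lapply(x$circuits, function(circ)
    data.frame(circuit_id = circ$circuit_id, pathway_id = circ$pathway_id,
               input = circ$input, output = circ$output,
               n_paths = length(circ$paths), truncated = circ$truncated,
               stringsAsFactors = FALSE)))
}
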