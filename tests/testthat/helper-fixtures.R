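# Shared fixtures and independent oracles for the test suite.

# minimal KGML document builder ------------------------------------------

kgml_doc <- function(entries, relations = "") {
  paste0('<?xml version="1.0"?>\n<pathway name="path:toy01" org="toy">\n',
         entries, "\n", relations, "\n</pathway>")
}

kgml_two_gene <- function(subtypes = '<subtype name="activation" value="--&gt;"/>') {
  kgml_doc(
    '<entry id="1" name="toy:g1" type="gene"/>
     <entry id="2" name="toy:g2" type="gene"/>',
    paste0('<relation entry1="1" entry2="2" type="PPrel">', subtypes,
           "</relation>"))
}

# independent Monte-Carlo oracle for circuit transmission ----------------
# Samples node states as independent Bernoulli draws and checks directly,
# per draw, whether any linear path transmits: every on-path node active,
# every external inhibitor of an on-path node inactive, an even number of
# in-path inhibition edges, and no on-path node inhibiting the same path.
# Shares no code with the inclusion-exclusion implementation.

oracle_circuit_probability <- function(paths, graph, node_probs, draws) {
  nodes <- names(node_probs)
  states <- matrix(stats::runif(length(nodes) * draws) < node_probs,
                   length(nodes), draws, dimnames = list(nodes, NULL))
  inh <- graph$edges[graph$edges$sign == "inhibition", , drop = FALSE]
  any_hit <- rep(FALSE, draws)
  for (p in paths) {
    consec <- if (length(p) > 1L)
      paste(p[-length(p)], p[-1L], sep = ">") else character(0)
    all_edges <- paste(graph$edges$from, graph$edges$to, sep = ">")
    n_inh_on_path <- sum(consec %in%
                           all_edges[graph$edges$sign == "inhibition"])
    if (n_inh_on_path %% 2L == 1L) next       # net-inhibitory delivery
    ext <- inh[inh$to %in% p &
                 !(paste(inh$from, inh$to, sep = ">") %in% consec), ,
               drop = FALSE]
    if (any(ext$from %in% p)) next            # self-contradictory path
    hit <- colSums(!states[p, , drop = FALSE]) == 0L
    if (nrow(ext))
      hit <- hit & colSums(states[unique(ext$from), , drop = FALSE]) == 0L
    any_hit <- any_hit | hit
  }
  mean(any_hit)
}

# brute-force all-simple-paths via igraph (enumeration oracle) ------------

igraph_simple_paths <- function(graph, from, to) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     vertices = names(graph$nodes))
  lapply(igraph::all_simple_paths(g, from, to, mode = "out"),
         function(p) names(p))
}

# nodes on directed cycles via igraph strong components (SCC oracle) ------

igraph_cycle_nodes <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     vertices = names(graph$nodes))
  comp <- igraph::components(g, mode = "strong")
  big <- which(tabulate(comp$membership) > 1L)
  names(graph$nodes)[comp$membership %in% big]
}

canon_paths <- function(paths) {
  sort(vapply(paths, paste, "", collapse = ">"))
}

random_node_probs <- function(graph) {
  stats::setNames(stats::runif(length(graph$nodes), 0.05, 0.95),
                  names(graph$nodes))
}
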