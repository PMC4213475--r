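#' Node-state requirements for signal transmission along one linear path
#'
#' A linear path transmits its signal when (a) every node on the path is
#' active and (b) every node that inhibits a node of the path is in a state
#' compatible with transmission, i.e. inactive. Inhibition edges lying on
#' the path itself are treated by parity: the source still transmits (it
#' must be active) but inverts the downstream signal, so a path delivers a
#' net-activating signal to the effector iff it carries an even number of
#' in-path inhibitions. A node required active (on the path) that also
#' inhibits another node of the same path is a contradiction: the
#' requirement set is inconsistent and the path event has probability 0.
#' This convention is isolated here so it can be swapped wholesale.
#'
#' @param path Character vector of node ids (a simple path in `graph`).
#' @param graph The [pathway_graph].
#' @return A list with `active` (node ids required active), `inactive`
#'   (external inhibitors required inactive), `n_inhib_on_path`,
#'   `net_activating` (even in-path inhibition parity) and `consistent`.
#' @export
path_requirements <- function(path, graph) {
  stopifnot(inherits(graph, "pathway_graph"), length(path) >= 1L)
  if (anyDuplicated(path)) stop("path_requirements: path is not simple")
  n_inhib <- 0L
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L)) {
      if (edge_sign(graph, path[i], path[i + 1L]) == "inhibition")
        n_inhib <- n_inhib + 1L
    }
  }
  # inhibitors of on-path nodes, excluding the path's own consecutive edges
  inh <- graph$edges[graph$edges$sign == "inhibition" &
                       graph$edges$to %in% path, , drop = FALSE]
  if (length(path) > 1L) {
    onpath <- paste(path[-length(path)], path[-1L], sep = "\r")
    inh <- inh[!(paste(inh$from, inh$to, sep = "\r") %in% onpath), ,
               drop = FALSE]
  }
  consistent <- !any(inh$from %in% path)
  list(active = path,
       inactive = sort(unique(inh$from[!(inh$from %in% path)])),
       n_inhib_on_path = n_inhib,
       net_activating = n_inhib %% 2L == 0L,
       consistent = consistent)
}

#' Probability of a requirement set being satisfied
#'
#' Node activations are treated as independent events: the probability is
#' the product of `P(active)` over nodes required active and `1 - P(active)`
#' over nodes required inactive. Inconsistent sets have probability 0. Nodes
#' with `NA` probability (unmeasured genes) are non-informative and are
#' skipped; the result then carries attribute `incomplete = TRUE`.
#'
#' @param requirements A [path_requirements()] result (or any list with
#'   `active`, `inactive`, `consistent`).
#' @param node_probs Named numeric vector, node id -> activation
#'   probability (`NA` allowed).
#' @return Probability in `[0, 1]`.
#' @export
path_probability <- function(requirements, node_probs) {
  if (!isTRUE(requirements$consistent)) return(0)
  pa <- node_probs[requirements$active]
  pi_ <- node_probs[requirements$inactive]
  incomplete <- anyNA(pa) || anyNA(pi_)
  p <- prod(pa[!is.na(pa)]) * prod(1 - pi_[!is.na(pi_)])
  structure(min(max(p, 0), 1), incomplete = incomplete)
}

#' Probability of signal transmission across a circuit
#'
#' The circuit transmits when at least one of its linear paths does; the
#' probability of this union of (generally overlapping) path events is
#' computed by inclusion-exclusion, with each intersection evaluated as the
#' probability of the union of the constituent requirement sets under node
#' independence — shared nodes thereby correlate path events correctly.
#' Paths delivering a net-inhibitory signal (odd in-path inhibition parity)
#' do not count as transmitting. Beyond `max_exact_paths` paths, the union
#' probability is estimated by Monte-Carlo sampling of independent node
#' states (result flagged `approximate`).
#'
#' @param circuit A circuit from [enumerate_circuits()], or a list of paths
#'   (character vectors).
#' @param graph The [pathway_graph].
#' @param node_probs Named numeric vector or nodes x samples matrix of
#'   activation probabilities.
#' @param max_exact_paths Cap on paths for exact inclusion-exclusion.
#' @param mc_draws Monte-Carlo draws for the fallback estimator.
#' @return Probability (or per-sample vector) in `[0, 1]`; attribute
#'   `approximate` marks Monte-Carlo results, `incomplete` marks skipped
#'   unmeasured nodes.
#' @export
circuit_probability <- function(circuit, graph, node_probs,
                                max_exact_paths = 20L, mc_draws = 1e5) {
  paths <- if (inherits(circuit, "circuit")) circuit$paths else circuit
  P <- if (is.matrix(node_probs)) node_probs else
    matrix(node_probs, ncol = 1, dimnames = list(names(node_probs), NULL))
  reqs <- lapply(paths, path_requirements, graph = graph)
  reqs <- Filter(function(r) r$consistent && r$net_activating, reqs)
  out <- union_probability(reqs, P, max_exact_paths, mc_draws)
  if (is.matrix(node_probs)) out else
    structure(as.numeric(out), approximate = attr(out, "approximate"),
              incomplete = attr(out, "incomplete"))
}

# union of requirement-set events over a node-prob matrix (nodes x samples);
# returns a per-sample vector
union_probability <- function(reqs, P, max_exact_paths, mc_draws) {
  ns <- ncol(P)
  zero <- structure(rep(0, ns), approximate = FALSE, incomplete = FALSE)
  if (length(reqs) == 0L) return(zero)
  missing_nodes <- rownames(P)[rowSums(is.na(P)) > 0L]
  incomplete <- FALSE
  if (length(missing_nodes)) {
    # unmeasured nodes are non-informative: dropped from every event
    touched <- any(vapply(reqs, function(r)
      any(c(r$active, r$inactive) %in% missing_nodes), TRUE))
    incomplete <- touched
    reqs <- lapply(reqs, function(r) {
      r$active <- setdiff(r$active, missing_nodes)
      r$inactive <- setdiff(r$inactive, missing_nodes)
      r
    })
  }
  n <- length(reqs)
  if (n <= max_exact_paths) {
    acc <- rep(0, ns)
    for (mask in seq_len(2^n - 1L)) {
      sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      act <- unique(unlist(lapply(reqs[sel], `[[`, "active")))
      ina <- unique(unlist(lapply(reqs[sel], `[[`, "inactive")))
      term <- if (length(intersect(act, ina))) rep(0, ns) else {
        t <- rep(1, ns)
        for (v in act) t <- t * P[v, ]
        for (v in ina) t <- t * (1 - P[v, ])
        t
      }
      acc <- acc + (-1)^(length(sel) + 1L) * term
    }
    structure(pmin(pmax(acc, 0), 1),
              approximate = FALSE, incomplete = incomplete)
  } else {
    nodes <- unique(unlist(lapply(reqs, function(r) c(r$active, r$inactive))))
    est <- numeric(ns)
    for (s in seq_len(ns)) {
      states <- matrix(stats::runif(length(nodes) * mc_draws) <
                         P[nodes, s], length(nodes), mc_draws,
                       dimnames = list(nodes, NULL))
      any_hit <- rep(FALSE, mc_draws)
      for (r in reqs) {
        hit <- rep(TRUE, mc_draws)
        for (v in r$active) hit <- hit & states[v, ]
        for (v in r$inactive) hit <- hit & !states[v, ]
        any_hit <- any_hit | hit
      }
      est[s] <- mean(any_hit)
    }
    structure(est, approximate = TRUE, incomplete = incomplete)
  }
}

#' Circuit x sample activity matrix
#'
#' Applies [circuit_probability()] per sample of a node-level activation
#' matrix for every circuit of a circuit set. Circuits all of whose path
#' nodes are unmeasured are dropped with a warning.
#'
#' @param circuits A `circuit_set` from [pathway_circuits()], or a plain
#'   list of circuits (then `graphs` must be supplied).
#' @param node_probs Matrix nodes x samples from [node_activation()] (or a
#'   simulated equivalent).
#' @param graphs List of [pathway_graph]s covering the circuits' pathways
#'   (taken from the circuit set when available).
#' @param ... Passed to [circuit_probability()].
#' @return Matrix circuits x samples of transmission probabilities, with
#'   attribute `pathway` (circuit -> pathway id) and `incomplete` (logical
#'   per circuit: some required nodes were unmeasured).
#' @export
circuit_activity <- function(circuits, node_probs, graphs = NULL, ...) {
  if (inherits(circuits, "circuit_set")) {
    if (is.null(graphs)) graphs <- circuits$graphs
    circuits <- circuits$circuits
  }
  stopifnot(is.matrix(node_probs), !is.null(graphs))
  gmap <- stats::setNames(graphs,
                          vapply(graphs, `[[`, "", "pathway_id"))
  rows <- list()
  pathway <- character(0)
  input <- character(0)
  output <- character(0)
  incomplete <- logical(0)
  for (circ in circuits) {
    g <- gmap[[circ$pathway_id]]
    if (is.null(g)) stop("no graph supplied for pathway '",
                         circ$pathway_id, "'")
    nodes_used <- unique(unlist(circ$paths, use.names = FALSE))
    if (all(rowSums(!is.na(node_probs[nodes_used, , drop = FALSE])) == 0L)) {
      warning("circuit '", circ$circuit_id,
              "' dropped: no member node measured", call. = FALSE)
      next
    }
    p <- circuit_probability(circ, g, node_probs, ...)
    key <- paste(circ$pathway_id, circ$circuit_id, sep = ":")
    rows[[key]] <- as.numeric(p)
    pathway[key] <- circ$pathway_id
    input[key] <- circ$input
    output[key] <- circ$output
    incomplete[key] <- isTRUE(attr(p, "incomplete"))
  }
  if (length(rows) == 0L) stop("no computable circuits")
  out <- do.call(rbind, rows)
  colnames(out) <- colnames(node_probs)
  attr(out, "pathway") <- pathway
  attr(out, "input") <- input
  attr(out, "output") <- output
  attr(out, "incomplete") <- incomplete
  out
}
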