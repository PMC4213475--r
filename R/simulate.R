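#' Deterministic toy pathway fixtures
#'
#' Builds a small set of pathway graphs exercising every topological
#' feature the model handles:
#' \describe{
#'   \item{`fig6`}{the worked-example topology with three receptors
#'     (ProtA, ProtC, ProtE), three effectors (ProtH, ProtI, ProtJ) and
#'     five circuits, the ProtA-to-ProtH circuit being traversable by the
#'     two linear paths ProtA,ProtB,ProtD,ProtF,ProtH and
#'     ProtA,ProtB,ProtD,ProtG,ProtH. Only those two path sequences and
#'     the 3-input/3-output/5-circuit structure are fixed by the source
#'     material; the remaining wiring is a minimal synthetic completion.}
#'   \item{`toycomplex`}{a chain containing a protein complex and an
#'     alternative-proteins node.}
#'   \item{`toyinhib`}{a chain with an external inhibitor.}
#'   \item{`toycycle`}{a pathway whose only routes traverse a 2-cycle, so
#'     all of its circuits are removed as loops.}
#'   \item{`rnd1`, `rnd2`}{seeded random DAGs with inhibitions and mixed
#'     node kinds (see [random_pathway()]).}
#' }
#'
#' @param seed Integer seed controlling the random DAG members.
#' @return Named list of [pathway_graph]s.
#' @export
toy_pathways <- function(seed = 1L) {
  single <- function(gene) list(kind = "single", genes = gene)
  fig6 <- pathway_graph(
    "fig6",
    nodes = stats::setNames(
      lapply(paste0("g", c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")),
             single),
      paste0("Prot", c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"))),
    edges = data.frame(
      from = c("ProtA", "ProtC", "ProtB", "ProtD", "ProtD", "ProtF",
               "ProtG", "ProtF", "ProtE"),
      to = c("ProtB", "ProtB", "ProtD", "ProtF", "ProtG", "ProtH",
             "ProtH", "ProtI", "ProtJ"),
      sign = "activation", stringsAsFactors = FALSE))
  toycomplex <- pathway_graph(
    "toycomplex",
    nodes = list(
      R1 = single("cx_r1"),
      CPX = list(kind = "complex", genes = c("cx_a", "cx_b")),
      ALT = list(kind = "alternatives", genes = c("cx_c", "cx_d")),
      EFF = single("cx_e")),
    edges = data.frame(from = c("R1", "CPX", "ALT"),
                       to = c("CPX", "ALT", "EFF"),
                       sign = "activation", stringsAsFactors = FALSE))
  toyinhib <- pathway_graph(
    "toyinhib",
    nodes = list(RA = single("in_a"), MB = single("in_b"),
                 EC = single("in_c"), INH = single("in_i")),
    edges = data.frame(from = c("RA", "MB", "INH"),
                       to = c("MB", "EC", "MB"),
                       sign = c("activation", "activation", "inhibition"),
                       stringsAsFactors = FALSE))
  toycycle <- pathway_graph(
    "toycycle",
    nodes = list(CA = single("cy_a"), CB = single("cy_b"),
                 CC = single("cy_c"), CD = single("cy_d")),
    edges = data.frame(from = c("CA", "CB", "CC", "CC"),
                       to = c("CB", "CC", "CB", "CD"),
                       sign = "activation", stringsAsFactors = FALSE))
  list(fig6 = fig6, toycomplex = toycomplex, toyinhib = toyinhib,
       toycycle = toycycle,
       rnd1 = random_pathway(8, seed = seed, pathway_id = "rnd1"),
       rnd2 = random_pathway(8, seed = seed + 1L, pathway_id = "rnd2"))
}

#' Random layered DAG pathway
#'
#' Generates a random acyclic signed pathway: nodes are ordered and edges
#' only run forward, so the graph is a DAG; a fraction of edges are
#' inhibitions and a fraction of nodes are alternatives or complex nodes
#' with two member genes.
#'
#' @param n_nodes Number of nodes.
#' @param edge_prob Probability of each forward edge.
#' @param inhib_prob Probability that an edge is an inhibition.
#' @param composite_prob Probability that a node is alternatives/complex.
#' @param seed Integer seed (deterministic output).
#' @param pathway_id Pathway id (also namespaces gene names).
#' @return A [pathway_graph].
#' @export
random_pathway <- function(n_nodes = 8L, edge_prob = 0.35,
                           inhib_prob = 0.25, composite_prob = 0.2,
                           seed = 1L, pathway_id = "random") {
  stopifnot(n_nodes >= 3L)
  rng <- local_rng(seed)
  ids <- sprintf("%s_n%02d", pathway_id, seq_len(n_nodes))
  nodes <- list()
  for (i in seq_len(n_nodes)) {
    r <- rng()
    if (r < composite_prob / 2) {
      nodes[[ids[i]]] <- list(kind = "alternatives",
                              genes = paste0(pathway_id, "_g", i,
                                             c("a", "b")))
    } else if (r < composite_prob) {
      nodes[[ids[i]]] <- list(kind = "complex",
                              genes = paste0(pathway_id, "_g", i,
                                             c("a", "b")))
    } else {
      nodes[[ids[i]]] <- list(kind = "single",
                              genes = paste0(pathway_id, "_g", i))
    }
  }
  from <- character(0); to <- character(0); sign <- character(0)
  for (i in seq_len(n_nodes - 1L)) {
    linked <- FALSE
    for (j in seq(i + 1L, n_nodes)) {
      if (rng() < edge_prob || (!linked && j == n_nodes)) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
        sign <- c(sign, if (rng() < inhib_prob) "inhibition" else
          "activation")
        linked <- TRUE
      }
    }
  }
  pathway_graph(pathway_id, nodes,
                data.frame(from = from, to = to, sign = sign,
                           stringsAsFactors = FALSE))
}

# private RNG stream that does not disturb the session RNG state
local_rng <- function(seed) {
  state <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  function(n = 1L) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    assign(".Random.seed", state, globalenv())
    x <- stats::runif(n)
    state <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  }
}

#' Probe map for a set of pathway graphs
#'
#' Assigns `probes_per_gene` synthetic probes to every gene of the supplied
#' graphs, emulating a microarray annotation table.
#'
#' @param graphs List of [pathway_graph]s.
#' @param probes_per_gene Probes per gene.
#' @return Data frame with columns `probe_id`, `gene_id`.
#' @export
fixture_probe_map <- function(graphs, probes_per_gene = 3L) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  genes <- unique(unlist(lapply(graphs, pathway_genes)))
  data.frame(
    probe_id = paste0(rep(genes, each = probes_per_gene), "_p",
                      seq_len(probes_per_gene)),
    gene_id = rep(genes, each = probes_per_gene),
    stringsAsFactors = FALSE)
}

#' Configuration for the null simulation
#'
#' Mirrors the null-simulation design used to measure the type I error of
#' the circuit test: datasets in which every probe of every gene carries
#' the same activation probability (a base value plus Gaussian noise), so
#' any circuit called differential between two halves of a dataset is a
#' false positive.
#'
#' @param n_datasets Datasets per (sample size, base probability) cell.
#' @param sample_sizes Integer vector of dataset sizes.
#' @param base_probabilities Base activation probabilities.
#' @param noise_sd Standard deviation of the zero-mean Gaussian probe noise.
#' @param seed Integer seed.
#' @return A list of class `null_sim_config`.
#' @export
null_sim_config <- function(n_datasets = 100L,
                            sample_sizes = c(10L, 20L, 50L, 100L),
                            base_probabilities = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            noise_sd = 0.05, seed = 1L) {
  stopifnot(n_datasets >= 1L, noise_sd >= 0,
            all(base_probabilities >= 0 & base_probabilities <= 1))
  structure(list(n_datasets = as.integer(n_datasets),
                 sample_sizes = as.integer(sample_sizes),
                 base_probabilities = base_probabilities,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "null_sim_config")
}

#' Simulate null probe-activation datasets
#'
#' For one cell of the null design, draws `n_datasets` probe x sample
#' matrices in which every entry is `base_p` plus Normal(0, `noise_sd`)
#' noise, clipped to `[0, 1]`. These are activation probabilities directly
#' (the mixture-fitting stage is bypassed, as in the type-I-error design).
#'
#' @param probes Character vector of probe ids.
#' @param n_samples Samples per dataset.
#' @param base_p Base activation probability.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_datasets Number of datasets.
#' @param seed Integer seed.
#' @return List of `n_datasets` matrices (probes x samples).
#' @export
simulate_null_probes <- function(probes, n_samples, base_p, noise_sd,
                                 n_datasets = 1L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_datasets), function(d) {
    m <- matrix(base_p + stats::rnorm(length(probes) * n_samples,
                                      0, noise_sd),
                length(probes), n_samples,
                dimnames = list(probes, paste0("s", seq_len(n_samples))))
    pmin(pmax(m, 0), 1)
  })
}

#' Null-simulation experiment: false-positive rate of the circuit test
#'
#' Runs the full type-I-error design: for every (sample size, base
#' probability) cell, simulates `n_datasets` null datasets, splits each
#' into two equal halves, aggregates probe probabilities to nodes, computes
#' circuit activities and tests every circuit; the false-positive rate is
#' the fraction of circuits with raw p below `alpha`.
#'
#' @param config A [null_sim_config()].
#' @param graphs List of [pathway_graph]s (default [toy_pathways()]).
#' @param probes_per_gene Probes simulated per gene.
#' @param alpha Raw p-value threshold counted as a (false) positive.
#' @return Data frame with columns `sample_size`, `base_p`, `fpr`
#'   (fraction of circuit tests with raw p below `alpha`), `fpr_fdr`
#'   (fraction called significant after within-pathway FDR correction —
#'   the rate of false calls the tool would actually report) and
#'   `n_tests`.
#' @export
run_null_experiment <- function(config = null_sim_config(),
                                graphs = NULL, probes_per_gene = 3L,
                                alpha = 0.05) {
  stopifnot(inherits(config, "null_sim_config"))
  if (is.null(graphs)) graphs <- toy_pathways(config$seed)
  cs <- pathway_circuits(graphs)
  if (length(cs$circuits) == 0L) stop("fixture pathways yield no circuits")
  pmap <- fixture_probe_map(graphs, probes_per_gene)
  grid <- expand.grid(sample_size = config$sample_sizes,
                      base_p = config$base_probabilities)
  grid$fpr <- NA_real_
  grid$fpr_fdr <- NA_real_
  grid$n_tests <- NA_integer_
  for (row in seq_len(nrow(grid))) {
    n <- grid$sample_size[row]
    if (n %% 2L == 1L) {
      message("odd sample size ", n, ": dropping one sample")
      n <- n - 1L
    }
    datasets <- simulate_null_probes(
      pmap$probe_id, n, grid$base_p[row], config$noise_sd,
      config$n_datasets,
      seed = config$seed + 7919L * row)
    group <- rep(c("half1", "half2"), each = n %/% 2L)
    hits <- 0L; fdr_hits <- 0L; total <- 0L
    for (d in datasets) {
      node_act <- node_activation(d, pmap, graphs)
      act <- suppressWarnings(circuit_activity(cs, node_act))
      res <- compare_conditions(act, group, alpha = alpha)
      hits <- hits + sum(res$p_value < alpha)
      fdr_hits <- fdr_hits + sum(res$direction != "none")
      total <- total + nrow(res)
    }
    grid$fpr[row] <- hits / total
    grid$fpr_fdr[row] <- fdr_hits / total
    grid$n_tests[row] <- total
  }
  grid
}

#' Simulate a two-condition expression study with known differential circuits
#'
#' End-to-end ground-truth generator. Every probe follows a two-component
#' normal mixture (inactive mean 5, active mean 9, both SD 1: roughly the
#' log2-scale separation of absent vs present transcripts on expression
#' arrays). A reference compendium is drawn with activation probability 0.5
#' per probe; study samples are drawn with a base activation probability,
#' and in condition 2 the genes of the designated circuits' nodes have
#' their activation probability shifted by `effect` (clipped to `[0, 1]`,
#' with a warning if clipping occurs).
#'
#' @param graphs List of [pathway_graph]s.
#' @param differential_circuits Character vector of circuit keys
#'   (`"pathway_id:input->output"`) whose node genes are shifted.
#' @param n_per_group Samples per condition.
#' @param effect Shift added to the activation probability in condition 2.
#' @param base_p Baseline activation probability of every gene.
#' @param n_ref Reference-compendium sample count.
#' @param probes_per_gene Probes per gene.
#' @param seed Integer seed.
#' @param mix_means,mix_sd Mixture component means (inactive, active) and
#'   common SD.
#' @return List with `expr` (study matrix, probes x samples), `compendium`,
#'   `probe_map`, `group` (condition factor), `truth` (keys of circuits
#'   sharing at least one shifted node — the circuits expected
#'   differential) and `shifted_genes`.
#' @export
simulate_study <- function(graphs, differential_circuits,
                           n_per_group = 20L, effect = 0.4,
                           base_p = 0.3, n_ref = 300L,
                           probes_per_gene = 3L, seed = 1L,
                           mix_means = c(5, 9), mix_sd = 1) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  cs <- pathway_circuits(graphs)
  keys <- vapply(cs$circuits, function(circ)
    paste(circ$pathway_id, circ$circuit_id, sep = ":"), "")
  miss <- setdiff(differential_circuits, keys)
  if (length(miss))
    stop("unknown differential circuit(s): ", paste(miss, collapse = ", "))
  pmap <- fixture_probe_map(graphs, probes_per_gene)
  gmap <- stats::setNames(graphs, vapply(graphs, `[[`, "", "pathway_id"))

  circuit_nodes <- function(circ) unique(unlist(circ$paths))
  target <- cs$circuits[keys %in% differential_circuits]
  shifted_nodes <- unique(unlist(lapply(target, circuit_nodes)))
  shifted_genes <- unique(unlist(lapply(target, function(circ) {
    g <- gmap[[circ$pathway_id]]
    unlist(lapply(circuit_nodes(circ), function(id) g$nodes[[id]]$genes))
  })))
  # any circuit sharing a shifted node is genuinely differential too
  truth <- keys[vapply(cs$circuits, function(circ)
    any(circuit_nodes(circ) %in% shifted_nodes), TRUE)]

  p2 <- base_p + effect
  if (p2 < 0 || p2 > 1) {
    warning("effect pushes activation probability outside [0,1]; clipped",
            call. = FALSE)
    p2 <- min(max(p2, 0), 1)
  }
  set.seed(seed)
  probes <- pmap$probe_id
  draw <- function(n, p_active) {
    active <- stats::runif(length(probes) * n) < p_active
    matrix(stats::rnorm(length(probes) * n,
                        ifelse(active, mix_means[2], mix_means[1]),
                        mix_sd),
           length(probes), n, dimnames = list(probes, NULL))
  }
  compendium <- draw(n_ref, 0.5)
  colnames(compendium) <- paste0("ref", seq_len(n_ref))
  g1 <- draw(n_per_group, base_p)
  # condition 2: shifted probability only on the designated circuits' genes
  p_by_probe <- ifelse(pmap$gene_id %in% shifted_genes, p2, base_p)
  active2 <- matrix(stats::runif(length(probes) * n_per_group) <
                      p_by_probe, length(probes), n_per_group)
  g2 <- matrix(stats::rnorm(length(probes) * n_per_group,
                            ifelse(active2, mix_means[2], mix_means[1]),
                            mix_sd),
               length(probes), n_per_group, dimnames = list(probes, NULL))
  expr <- cbind(g1, g2)
  colnames(expr) <- c(paste0("c1_", seq_len(n_per_group)),
                      paste0("c2_", seq_len(n_per_group)))
  list(expr = expr, compendium = compendium, probe_map = pmap,
       group = factor(rep(c("condition1", "condition2"),
                          each = n_per_group)),
       truth = truth, shifted_genes = shifted_genes)
}
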