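#' Fit a two-component mixture to a feature's reference expression values
#'
#' Expression values of a gene across a large reference compendium are
#' modeled as a mixture of an inactive (low-expression) and an active
#' (high-expression) component. The inactive component may be gamma
#' (generalising the exponential shape typical of absent transcripts) or
#' normal; the active component is normal. Fitting is by
#' expectation-maximization, initialised at the two highest peaks of a
#' kernel-density estimate of the values; among the candidate family pairs
#' the best log-likelihood wins (BIC tie-break). The lower-mean component is
#' labeled inactive.
#'
#' @param values Numeric vector of reference expression values
#'   (at least 30 finite values with positive variance).
#' @param families Candidate family pairs to fit, a subset of
#'   `"normal-normal"` and `"gamma-normal"` (inactive family named first).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `mixture_model` with components `family_inactive`,
#'   `family_active`, `params_inactive`, `params_active` (location/scale for
#'   normal, shape/scale for gamma), `pi0`, `pi1`, `mean_inactive`,
#'   `mean_active`, `loglik`, `converged`, `degenerate`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(800, 4, 1), rnorm(1200, 9, 1))
#' m <- fit_mixture(x)
#' coef(m)
#' posterior_active(6.5, m)
#' @export
fit_mixture <- function(values,
                        families = c("normal-normal", "gamma-normal"),
                        max_iter = 500L, tol = 1e-8) {
  values <- values[is.finite(values)]
  if (length(values) < 30L)
    stop("fit_mixture: need at least 30 finite values")
  if (stats::var(values) <= 0)
    stop("fit_mixture: zero-variance input")
  families <- match.arg(families, c("normal-normal", "gamma-normal"),
                        several.ok = TRUE)
  if (any(values <= 0) && "gamma-normal" %in% families)
    families <- setdiff(families, "gamma-normal")
  if (length(families) == 0L)
    stop("fit_mixture: no admissible family pair (non-positive values?)")

  init <- kde_two_peaks(values)
  fits <- lapply(families, function(fam)
    em_two_component(values, fam, init, max_iter, tol))
  # log-likelihood selection; all candidate pairs have five free parameters,
  # so BIC ranks identically and only breaks exact ties by family order
  ll <- vapply(fits, `[[`, 0, "loglik")
  best <- fits[[which.max(ll)]]
  best$n <- length(values)
  class(best) <- "mixture_model"
  best
}

# locate the two highest peaks of a kernel density estimate; fall back to
# lower/upper quartiles when the distribution is unimodal
kde_two_peaks <- function(values) {
  d <- stats::density(values, n = 512)
  y <- d$y
  is_peak <- c(FALSE, y[2:511] > y[1:510] & y[2:511] >= y[3:512], FALSE)
  px <- d$x[is_peak]
  py <- y[is_peak]
  if (length(px) >= 2L) {
    top <- order(py, decreasing = TRUE)[1:2]
    sort(px[top])
  } else {
    stats::quantile(values, c(0.25, 0.75), names = FALSE)
  }
}

em_two_component <- function(values, family, init, max_iter, tol) {
  fam0 <- strsplit(family, "-")[[1]][1]
  n <- length(values)
  s <- stats::sd(values)
  # moments-based start around the two KDE modes
  mu <- init
  sd0 <- sd1 <- max(s / 2, 1e-3)
  pi1 <- mean(values > mean(init))
  pi1 <- min(max(pi1, 0.05), 0.95)
  theta0 <- list(mean = mu[1], sd = sd0)  # normal parametrisation throughout;
  theta1 <- list(mean = mu[2], sd = sd1)  # gamma converts via moment matching
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d0 <- comp_density(values, fam0, theta0)
    d1 <- comp_density(values, "normal", theta1)
    num1 <- pi1 * d1
    tot <- (1 - pi1) * d0 + num1
    tot[tot <= 0] <- .Machine$double.xmin
    w <- num1 / tot          # responsibility of the active component
    ll <- sum(log(tot))
    if (is.finite(ll) && is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    pi1 <- mean(w)
    pi1 <- min(max(pi1, 1e-6), 1 - 1e-6)
    theta1 <- wmoments(values, w)
    theta0 <- wmoments(values, 1 - w)
  }
  # orient: lower-mean component is inactive
  if (theta0$mean > theta1$mean) {
    tmp <- theta0; theta0 <- theta1; theta1 <- tmp
    pi1 <- 1 - pi1
    if (fam0 != "normal") {
      # gamma was fitted on what turned out to be the active side; refit the
      # orientation-consistent normal-normal solution instead
      return(em_two_component(values, "normal-normal", init, max_iter, tol))
    }
  }
  sep <- abs(theta1$mean - theta0$mean) /
    max(sqrt((theta0$sd^2 + theta1$sd^2) / 2), 1e-12)
  degenerate <- !converged || pi1 < 0.02 || pi1 > 0.98 || sep < 0.5
  params0 <- if (fam0 == "gamma") gamma_from_moments(theta0) else
    list(mean = theta0$mean, sd = theta0$sd)
  list(family_inactive = fam0, family_active = "normal",
       params_inactive = params0,
       params_active = list(mean = theta1$mean, sd = theta1$sd),
       pi0 = 1 - pi1, pi1 = pi1,
       mean_inactive = theta0$mean, mean_active = theta1$mean,
       loglik = ll_old, converged = converged, degenerate = degenerate)
}

wmoments <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  v <- sum(w * (x - m)^2) / sw
  list(mean = m, sd = sqrt(max(v, 1e-6)))
}

# component density in the mean/sd parametrisation; the gamma component uses
# moment matching (shape = m^2/v, scale = v/m), the closed-form weighted
# M-step for the gamma shape having no solution
comp_density <- function(x, family, theta) {
  if (family == "normal") {
    stats::dnorm(x, theta$mean, theta$sd)
  } else {
    g <- gamma_from_moments(theta)
    stats::dgamma(x, shape = g$shape, scale = g$scale)
  }
}

gamma_from_moments <- function(theta) {
  m <- max(theta$mean, 1e-9)
  v <- max(theta$sd^2, 1e-9)
  list(shape = m^2 / v, scale = v / m)
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("<mixture_model> ", x$family_inactive, "+", x$family_active,
      " (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  inactive: pi0 = %.3f, mean = %.3f\n", x$pi0, x$mean_inactive))
  cat(sprintf("  active:   pi1 = %.3f, mean = %.3f\n", x$pi1, x$mean_active))
  if (x$degenerate) cat("  flagged degenerate\n")
  invisible(x)
}

#' @export
coef.mixture_model <- function(object, ...) {
  c(pi0 = object$pi0, pi1 = object$pi1,
    mean_inactive = object$mean_inactive,
    mean_active = object$mean_active,
    unlist(object$params_inactive) |>
      stats::setNames(paste0("inactive_", names(object$params_inactive))),
    unlist(object$params_active) |>
      stats::setNames(paste0("active_", names(object$params_active))))
}

#' @export
predict.mixture_model <- function(object, newdata, ...) {
  posterior_active(newdata, object)
}

#' @export
simulate.mixture_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  active <- stats::runif(nsim) < object$pi1
  out <- numeric(nsim)
  out[active] <- stats::rnorm(sum(active), object$params_active$mean,
                              object$params_active$sd)
  n0 <- sum(!active)
  out[!active] <- if (object$family_inactive == "gamma")
    stats::rgamma(n0, shape = object$params_inactive$shape,
                  scale = object$params_inactive$scale)
  else stats::rnorm(n0, object$params_inactive$mean,
                    object$params_inactive$sd)
  out
}

#' Posterior probability of activity given an expression value
#'
#' Applies Bayes' theorem to a fitted mixture:
#' `P(active | x) = pi1 p1(x) / (pi0 p0(x) + pi1 p1(x))`.
#' When both densities underflow to zero deep in the tails, the posterior is
#' resolved by side: 1 above the active-component mean, 0 below.
#'
#' @param x Numeric vector of expression values.
#' @param model A [fit_mixture()] result.
#' @return Posterior probabilities in `[0, 1]`, same length as `x`.
#' @export
posterior_active <- function(x, model) {
  stopifnot(inherits(model, "mixture_model"))
  d0 <- comp_density_fitted(x, model$family_inactive, model$params_inactive)
  d1 <- stats::dnorm(x, model$params_active$mean, model$params_active$sd)
  num <- model$pi1 * d1
  den <- model$pi0 * d0 + num
  p <- ifelse(den > 0, num / den, as.numeric(x >= model$mean_active))
  pmin(pmax(p, 0), 1)
}

comp_density_fitted <- function(x, family, params) {
  if (family == "gamma")
    stats::dgamma(x, shape = params$shape, scale = params$scale)
  else
    stats::dnorm(x, params$mean, params$sd)
}

#' Fit mixtures for every feature of a reference compendium
#'
#' @param compendium Numeric matrix, features x reference samples, with
#'   rownames.
#' @param ... Passed to [fit_mixture()].
#' @return Object of class `mixture_models`: named list of `mixture_model`
#'   fits.
#' @export
fit_mixtures <- function(compendium, ...) {
  stopifnot(is.matrix(compendium), !is.null(rownames(compendium)))
  fits <- lapply(seq_len(nrow(compendium)), function(i)
    fit_mixture(compendium[i, ], ...))
  names(fits) <- rownames(compendium)
  structure(fits, class = "mixture_models")
}

#' @export
print.mixture_models <- function(x, ...) {
  deg <- sum(vapply(x, `[[`, TRUE, "degenerate"))
  cat("<mixture_models> ", length(x), " feature(s), ",
      deg, " flagged degenerate\n", sep = "")
  invisible(x)
}

#' Percentile aggregation of activation probabilities
#'
#' Summarises a set of probability values by their `q`-th percentile with
#' linear interpolation. The 90th percentile is used probe-to-gene and over
#' alternatives nodes: the highest hybridisation signals evidence gene
#' activity while the very top is avoided as outlier-prone.
#'
#' @param p Non-empty numeric vector of probabilities.
#' @param q Percentile in `[0, 100]` (default 90).
#' @return The interpolated percentile.
#' @export
aggregate_percentile <- function(p, q = 90) {
  if (length(p) == 0L) stop("aggregate_percentile: empty input")
  stats::quantile(p, q / 100, names = FALSE, type = 7)
}

#' Discard probes mapping to multiple genes
#'
#' @param probe_map Data frame with columns `probe_id`, `gene_id`.
#' @return The map restricted to probes hitting exactly one distinct gene;
#'   the number of discarded probes is reported via a message.
#' @export
drop_multimapping_probes <- function(probe_map) {
  stopifnot(all(c("probe_id", "gene_id") %in% names(probe_map)))
  probe_map <- unique(probe_map[c("probe_id", "gene_id")])
  ngenes <- tapply(probe_map$gene_id, probe_map$probe_id,
                   function(g) length(unique(g)))
  multi <- names(ngenes)[ngenes > 1L]
  out <- probe_map[!(probe_map$probe_id %in% multi), , drop = FALSE]
  if (nrow(out) == 0L)
    stop("all probes map to multiple genes; nothing left to analyse")
  if (length(multi))
    message(length(multi), " multi-mapping probe(s) discarded")
  rownames(out) <- NULL
  out
}

#' Probe-level activation probabilities for a study matrix
#'
#' @param expr Numeric matrix, probes x samples, rownames = probe ids.
#' @param models A `mixture_models` object fitted on the reference
#'   compendium, covering (at least) the probes of `expr`.
#' @return Matrix of posterior activation probabilities, probes x samples;
#'   probes without a fitted model are dropped with a warning.
#' @export
probe_activation <- function(expr, models) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            inherits(models, "mixture_models"))
  have <- rownames(expr) %in% names(models)
  if (!all(have)) {
    warning(sum(!have), " probe(s) without a fitted mixture dropped",
            call. = FALSE)
    expr <- expr[have, , drop = FALSE]
  }
  if (nrow(expr) == 0L) stop("no probes with fitted mixtures")
  out <- expr
  for (i in seq_len(nrow(expr)))
    out[i, ] <- posterior_active(expr[i, ], models[[rownames(expr)[i]]])
  out
}

#' Gene-level activation probabilities
#'
#' Aggregates probe activation probabilities to genes by the 90th
#' percentile over each gene's probes, per sample.
#'
#' @param probe_probs Matrix probes x samples of activation probabilities.
#' @param probe_map Data frame `probe_id`, `gene_id` (multi-mapping probes
#'   are discarded first).
#' @param q Aggregation percentile.
#' @return Matrix genes x samples.
#' @export
gene_activation <- function(probe_probs, probe_map, q = 90) {
  probe_map <- drop_multimapping_probes(probe_map)
  probe_map <- probe_map[probe_map$probe_id %in% rownames(probe_probs), ,
                         drop = FALSE]
  if (nrow(probe_map) == 0L) stop("no mapped probes present in the matrix")
  genes <- unique(probe_map$gene_id)
  out <- matrix(NA_real_, length(genes), ncol(probe_probs),
                dimnames = list(genes, colnames(probe_probs)))
  by_gene <- split(probe_map$probe_id, probe_map$gene_id)
  for (g in genes) {
    sub <- probe_probs[by_gene[[g]], , drop = FALSE]
    out[g, ] <- apply(sub, 2, aggregate_percentile, q = q)
  }
  out
}

#' Activation probability of a single pathway node
#'
#' A single-protein node takes its gene's probability; an
#' alternative-proteins node (redundant members) takes the 90th percentile
#' over all probes of all member genes (falling back to member gene
#' probabilities when probe-level values are not supplied); a complex node
#' takes the minimum over member probabilities — the least available
#' member limits the complex's integrity.
#'
#' @param node A [node_spec()].
#' @param gene_probs Named numeric vector, gene -> activation probability.
#' @param probe_probs Optional named numeric vector of probe probabilities.
#' @param probe_map Optional data frame `probe_id`, `gene_id` (required with
#'   `probe_probs`).
#' @param q Aggregation percentile for alternatives nodes.
#' @return Probability in `[0, 1]`, or `NA` if none of the node's genes is
#'   measured.
#' @export
node_probability <- function(node, gene_probs, probe_probs = NULL,
                             probe_map = NULL, q = 90) {
  node <- validate_node_spec(node, "<node>")
  present <- intersect(node$genes, names(gene_probs))
  if (length(present) == 0L) return(NA_real_)
  switch(node$kind,
    single = unname(gene_probs[present]),
    complex = min(gene_probs[present]),
    alternatives = {
      if (!is.null(probe_probs) && !is.null(probe_map)) {
        probes <- probe_map$probe_id[probe_map$gene_id %in% node$genes]
        probes <- intersect(probes, names(probe_probs))
        if (length(probes))
          return(aggregate_percentile(probe_probs[probes], q))
      }
      aggregate_percentile(gene_probs[present], q)
    })
}

#' Node-level activation matrix for one or more pathways
#'
#' Builds the node x sample activation matrix feeding signal propagation.
#' Alternatives nodes pool the probe-level probabilities of all member
#' genes; complex nodes take the per-sample minimum over member gene
#' probabilities; nodes none of whose genes are measured get `NA` rows
#' (excluded from path products downstream, with a completeness flag).
#'
#' @param probe_probs Matrix probes x samples of activation probabilities.
#' @param probe_map Data frame `probe_id`, `gene_id`.
#' @param graphs A [pathway_graph] or list of them.
#' @param q Aggregation percentile.
#' @return Matrix nodes x samples (node ids as rownames).
#' @export
node_activation <- function(probe_probs, probe_map, graphs, q = 90) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  probe_map <- drop_multimapping_probes(probe_map)
  probe_map <- probe_map[probe_map$probe_id %in% rownames(probe_probs), ,
                         drop = FALSE]
  gene_probs <- gene_activation(probe_probs, probe_map, q = q)
  nodes <- unlist(lapply(graphs, function(g) names(g$nodes)),
                  use.names = FALSE)
  if (anyDuplicated(nodes))
    stop("node ids collide across pathways; namespace them by pathway id")
  out <- matrix(NA_real_, length(nodes), ncol(probe_probs),
                dimnames = list(nodes, colnames(probe_probs)))
  for (g in graphs) {
    for (id in names(g$nodes)) {
      node <- g$nodes[[id]]
      present <- intersect(node$genes, rownames(gene_probs))
      if (length(present) == 0L) next
      out[id, ] <- switch(node$kind,
        single = gene_probs[present, ],
        complex = apply(gene_probs[present, , drop = FALSE], 2, min),
        alternatives = {
          probes <- probe_map$probe_id[probe_map$gene_id %in% node$genes]
          if (length(probes))
            apply(probe_probs[probes, , drop = FALSE], 2,
                  aggregate_percentile, q = q)
          else apply(gene_probs[present, , drop = FALSE], 2,
                     aggregate_percentile, q = q)
        })
    }
  }
  out
}
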