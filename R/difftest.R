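#' Wilcoxon rank-sum comparison of one circuit between two conditions
#'
#' Unpaired two-sample Wilcoxon rank-sum test on a circuit's per-sample
#' transmission probabilities, with tie correction; the p-value is exact
#' when both groups have at most 25 samples and no ties occur, otherwise a
#' tie-corrected normal approximation is used (the convention of
#' [stats::wilcox.test()]). The location estimate is the Hodges-Lehmann
#' shift of condition 2 relative to condition 1 (median of pairwise
#' differences `g2 - g1`); its sign indicates the activated condition.
#'
#' @param g1,g2 Numeric vectors of circuit activation probabilities for the
#'   two conditions (each of length >= 2).
#' @return List with `p_value` and `location` (Hodges-Lehmann estimate of
#'   the condition-2 minus condition-1 shift).
#' @export
wilcoxon_circuit <- function(g1, g2) {
  if (length(g1) < 2L || length(g2) < 2L)
    stop("wilcoxon_circuit: each group needs at least 2 samples")
  if (anyNA(g1) || anyNA(g2))
    stop("wilcoxon_circuit: missing values in activity probabilities")
  diffs <- outer(g2, g1, "-")
  location <- stats::median(diffs)
  if (all(diffs == 0))                       # constant and equal groups
    return(list(p_value = 1, location = 0))
  wt <- suppressWarnings(stats::wilcox.test(g2, g1, exact = NULL,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1                      # all-tied degenerate case
  list(p_value = p, location = location)
}

#' FDR adjustment of circuit p-values within pathways
#'
#' Benjamini-Hochberg step-up adjustment applied separately to each
#' pathway's set of circuit p-values (the default), or across all circuits
#' at once (`scope = "global"`), useful for multi-pathway runs.
#'
#' @param p Numeric vector of p-values.
#' @param pathway Character vector, same length, assigning each p-value to
#'   a pathway (ignored for `scope = "global"`).
#' @param scope `"pathway"` or `"global"`.
#' @return Adjusted p-values, same order as `p`.
#' @export
adjust_fdr <- function(p, pathway = NULL, scope = c("pathway", "global")) {
  scope <- match.arg(scope)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (scope == "global" || is.null(pathway))
    return(stats::p.adjust(p, method = "BH"))
  stopifnot(length(pathway) == length(p))
  out <- p
  for (pw in unique(pathway)) {
    i <- pathway == pw
    out[i] <- stats::p.adjust(p[i], method = "BH")
  }
  out
}

#' Differential circuit activation between two conditions
#'
#' Tests every circuit of an activity matrix for a difference in
#' signal-transmission probability between two sample groups (Wilcoxon
#' rank-sum), controls the false discovery rate, and reports the direction
#' of activation from the sign of the Hodges-Lehmann location estimate.
#'
#' @param activity Circuits x samples matrix from [circuit_activity()].
#' @param group Factor or vector over the samples (columns) with exactly
#'   two levels; the second level is "condition 2".
#' @param alpha Significance level on the FDR-adjusted p-value.
#' @param fdr_scope `"pathway"` (adjust within each pathway) or `"global"`.
#' @return Data frame of class `circuit_results` with columns `circuit_id`,
#'   `pathway_id`, `input`, `output`, `p_value`, `fdr_p`, `location`,
#'   `direction` (`up_in_condition2` / `down_in_condition2` / `none`).
#' @export
compare_conditions <- function(activity, group, alpha = 0.05,
                               fdr_scope = c("pathway", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(is.matrix(activity), alpha > 0, alpha <= 1)
  group <- as.factor(group)
  if (nlevels(group) != 2L)
    stop("compare_conditions: exactly two groups required, got ",
         nlevels(group))
  if (length(group) != ncol(activity))
    stop("compare_conditions: design length does not match sample count")
  g1 <- group == levels(group)[1]
  g2 <- group == levels(group)[2]
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop("compare_conditions: each group needs at least 2 samples")
  pathway <- attr(activity, "pathway")
  if (is.null(pathway))
    pathway <- stats::setNames(rep("pathway", nrow(activity)),
                               rownames(activity))
  res <- lapply(seq_len(nrow(activity)), function(i)
    wilcoxon_circuit(activity[i, g1], activity[i, g2]))
  p <- vapply(res, `[[`, 0, "p_value")
  loc <- vapply(res, `[[`, 0, "location")
  ids <- rownames(activity)
  input <- attr(activity, "input")
  output <- attr(activity, "output")
  if (is.null(input) || is.null(output)) {
    io <- strsplit(sub("^[^:]*:", "", ids), "->", fixed = TRUE)
    input <- stats::setNames(vapply(io, `[`, "", 1L), ids)
    output <- stats::setNames(vapply(io, function(x) x[length(x)], ""), ids)
  }
  fdr <- adjust_fdr(p, pathway[ids], scope = fdr_scope)
  direction <- ifelse(fdr < alpha & loc > 0, "up_in_condition2",
                      ifelse(fdr < alpha & loc < 0, "down_in_condition2",
                             "none"))
  out <- data.frame(
    circuit_id = ids,
    pathway_id = unname(pathway[ids]),
    input = unname(input[ids]),
    output = unname(output[ids]),
    p_value = p, fdr_p = fdr, location = loc, direction = direction,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "groups") <- levels(group)
  class(out) <- c("circuit_results", "data.frame")
  out
}

#' @export
print.circuit_results <- function(x, digits = 4, ...) {
  alpha <- attr(x, "alpha")
  cat("Differential circuit activation (",
      paste(attr(x, "groups"), collapse = " vs "),
      "), ", nrow(x), " circuit(s), FDR alpha = ", alpha, "\n\n", sep = "")
  df <- as.data.frame(x)
  df$p_value <- signif(df$p_value, digits)
  df$fdr_p <- signif(df$fdr_p, digits)
  df$location <- signif(df$location, digits)
  print.data.frame(df[order(df$p_value), ], row.names = FALSE)
  invisible(x)
}
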