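#' Simulate the attractor corresponding to one experiment
#'
#' Follows the steady-state protocol: the initial state is the Boolean
#' expression of the row's base wild-type experiment (a wild-type row is its
#' own base), the mutated gene is clamped to 0 for a knockout or 1 for an
#' overexpression (no clamp for wild type), and the synchronous trajectory
#' is run to its attractor.
#'
#' @param net a [boolean_network()] (the candidate/inferred network).
#' @param row experiment row index or id.
#' @param dataset an [expression_dataset()] with a Boolean matrix.
#' @param max_steps passed to [find_attractor()].
#' @return A `bn_attractor`.
#' @export
simulate_experiment <- function(net, row, dataset, max_steps = 2000) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.character(row)) row <- match(row, dataset$annotations$id)
  if (is.na(row) || row < 1 || row > n_experiments(dataset))
    stop("unknown experiment row")
  plan <- simulation_plan(dataset)
  clamps <- NULL
  if (plan$clamp_gene[row] > 0)
    clamps <- setNames(plan$clamp_val[row], net$genes[plan$clamp_gene[row]])
  find_attractor(net, plan$inits[row, ], clamps = clamps, max_steps = max_steps)
}

# Per-row initial states and clamps implied by the annotations.
simulation_plan <- function(dataset) {
  if (is.null(dataset$bool)) stop("dataset carries no Boolean matrix")
  ann <- dataset$annotations
  base <- base_wt_index(dataset)
  inits <- dataset$bool[base, , drop = FALSE]
  clamp_gene <- ifelse(ann$ET == "WT", 0L, match(ann$MG, dataset$genes))
  clamp_val <- ifelse(ann$ET == "OE", 1L, 0L)
  clamp_val[ann$ET == "WT"] <- 0L
  list(inits = inits, clamp_gene = as.integer(clamp_gene),
       clamp_val = as.integer(clamp_val))
}

#' Similarity between an observed steady state and an attractor
#'
#' Per-gene similarity `s_i` is the fraction of the attractor's states in
#' which gene `i` equals its observed value; the state similarity `s` is
#' the mean of `s_i` over genes.
#'
#' @param e observed Boolean expression vector.
#' @param attractor a `bn_attractor` (or a 0/1 state matrix).
#' @return List with `s` (scalar in `[0,1]`) and `per_gene` (`s_i` vector).
#' @export
state_similarity <- function(e, attractor) {
  states <- if (inherits(attractor, "bn_attractor")) attractor$states else attractor
  if (ncol(states) != length(e)) stop("dimension mismatch")
  per_gene <- colMeans(states == rep(e, each = nrow(states)))
  list(s = mean(per_gene), per_gene = unname(per_gene))
}

#' Dynamics accuracy of a network on a steady-state dataset
#'
#' Every experiment is simulated with [simulate_experiment()] semantics and
#' compared to its observed Boolean steady state; the dynamics accuracy is
#' the mean state similarity over experiments. Per-gene averages (the mean
#' of `s_i` over experiments) are reported as well; they drive the
#' mutation-gene choice of the genetic algorithm.
#'
#' @inheritParams simulate_experiment
#' @return A `dynamics_report`: list with `dynamics_accuracy`,
#'   `per_experiment` (named vector), `per_gene` (named vector of
#'   experiment-averaged `s_i`), `s_gene` (experiments x genes matrix of
#'   `s_i`) and `truncated` (per-experiment flags).
#' @export
dynamics_accuracy <- function(net, dataset, max_steps = 2000) {
  stopifnot(inherits(net, "boolean_network"),
            inherits(dataset, "expression_dataset"))
  if (n_experiments(dataset) == 0) stop("empty dataset")
  if (!identical(net$genes, dataset$genes))
    stop("network and dataset gene sets differ")
  plan <- simulation_plan(dataset)
  fl <- flatten_network(net)
  res <- cpp_dynamics(fl$nreg, fl$reg, fl$I, fl$O, fl$def, plan$inits,
                      plan$clamp_gene, plan$clamp_val, dataset$bool,
                      as.integer(max_steps))
  per_exp <- setNames(res$per_experiment, dataset$annotations$id)
  dimnames(res$s_gene) <- list(dataset$annotations$id, net$genes)
  structure(list(dynamics_accuracy = mean(per_exp),
                 per_experiment = per_exp,
                 per_gene = colMeans(res$s_gene),
                 s_gene = res$s_gene,
                 truncated = setNames(res$truncated, dataset$annotations$id)),
            class = "dynamics_report")
}

edge_keys <- function(edges, signed = TRUE) {
  if (signed) paste(edges$from, edges$to, edges$sign)
  else unique(paste(edges$from, edges$to))
}

#' Structural comparison of an inferred network against a gold standard
#'
#' Counts true/false positives and negatives over the `2 N (N - 1)` possible
#' signed directed interactions (each ordered gene pair can carry an
#' activating and an inhibiting edge): an edge inferred with the wrong sign
#' is a false positive, and its true counterpart a false negative. With
#' `signed = FALSE` the comparison ignores signs and the universe shrinks to
#' `N (N - 1)` ordered pairs (useful when scoring tools that output unsigned
#' networks). Precision is defined as 0 when nothing is predicted.
#'
#' @param inferred,truth [boolean_network()]s or edge data frames with
#'   columns `from`, `to`, `sign`.
#' @param N number of genes; inferred from a network argument when omitted.
#' @param signed compare signed (default) or unsigned edges.
#' @return A `structural_report`: list with counts `tp`, `fp`, `fn`, `tn`
#'   and metrics `precision`, `recall`, `structural_accuracy`.
#' @export
structural_metrics <- function(inferred, truth, N = NULL, signed = TRUE) {
  as_edges <- function(x) if (inherits(x, "boolean_network")) network_edges(x) else x
  if (is.null(N)) {
    for (x in list(inferred, truth))
      if (inherits(x, "boolean_network")) N <- n_genes(x)
    if (is.null(N)) stop("N must be given when both arguments are edge frames")
  }
  a <- unique(edge_keys(as_edges(inferred), signed))
  b <- unique(edge_keys(as_edges(truth), signed))
  universe <- as.integer(if (signed) 2 * N * (N - 1) else N * (N - 1))
  tp <- length(intersect(a, b))
  fp <- length(setdiff(a, b))
  fn <- length(setdiff(b, a))
  tn <- universe - tp - fp - fn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = if (tp + fp == 0) 0 else tp / (tp + fp),
                 recall = if (tp + fn == 0) 0 else tp / (tp + fn),
                 structural_accuracy = (tp + tn) / universe,
                 signed = signed, n_genes = N),
            class = "structural_report")
}

#' @export
print.structural_report <- function(x, ...) {
  cat(sprintf(
    "Structural report (%s): TP=%d FP=%d FN=%d TN=%d\n precision=%.4f recall=%.4f accuracy=%.4f\n",
    if (x$signed) "signed" else "unsigned", x$tp, x$fp, x$fn, x$tn,
    x$precision, x$recall, x$structural_accuracy))
  invisible(x)
}

#' @export
print.dynamics_report <- function(x, ...) {
  cat(sprintf("Dynamics accuracy: %.4f over %d experiments", x$dynamics_accuracy,
              length(x$per_experiment)))
  if (any(x$truncated)) cat(" [", sum(x$truncated), "truncated ]")
  cat("\n")
  invisible(x)
}
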