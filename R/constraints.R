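#' Constraint derivation parameters
#'
#' `alpha` is the correlation floor below which a gene pair is considered
#' unrelated; `beta` is the directness threshold above which a strong
#' correlation is read as a direct interaction. Defaults follow the usual
#' heuristic choice alpha = 0.1, beta = 0.5.
#'
#' @param alpha correlation floor, `0 <= alpha < beta`.
#' @param beta directness threshold, `alpha < beta <= 1`.
#' @export
constraint_params <- function(alpha = 0.1, beta = 0.5) {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  if (!(alpha >= 0 && alpha < beta && beta <= 1))
    stop("need 0 <= alpha < beta <= 1")
  structure(list(alpha = alpha, beta = beta), class = "constraint_params")
}

#' Gene-gene coherency between a perturbation row and its base wild type
#'
#' For mutated gene `k` and another gene `l`, the coherency is
#' `(e_k - w_k) * (e_l - w_l)`: +1 when both genes change in the same
#' direction relative to the wild type, -1 when they change oppositely,
#' 0 when either does not change.
#'
#' @param e Boolean expression vector of the perturbation experiment.
#' @param w Boolean expression vector of its base wild-type experiment.
#' @param k index of the mutated gene.
#' @param l index of the probed gene, `l != k`.
#' @return -1, 0 or +1.
#' @export
coherency <- function(e, w, k, l) {
  if (l == k) stop("coherency is undefined for the mutated gene itself")
  as.integer((e[k] - w[k]) * (e[l] - w[l]))
}

#' Pearson correlation of two genes over all experiments
#'
#' Computed over every row of the Boolean matrix; defined as 0 when either
#' gene has zero variance (a constant gene supports no constraint).
#'
#' @param E Boolean matrix, experiments x genes.
#' @param k,l gene column indices.
#' @export
gene_correlation <- function(E, k, l) {
  if (nrow(E) < 2) stop("need at least two experiments")
  r <- suppressWarnings(cor(E[, k], E[, l]))
  if (is.na(r)) 0 else r
}

# Full correlation matrix with zero-variance columns mapped to 0.
correlation_matrix <- function(E) {
  r <- suppressWarnings(cor(E))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r
}

#' Classify one gene pair into a path-consistency constraint class
#'
#' Implements the two-criterion table: the positiveness condition requires
#' the aggregated coherency and the correlation to share a sign; the
#' directness condition reads `|r| >= beta` as a direct interaction and
#' `alpha < |r| < beta` as an indirect path. `|r| <= alpha` (or a sign
#' mismatch, or zero coherency) yields no constraint.
#'
#' @param delta aggregated coherency sign (-1, 0 or +1).
#' @param r Pearson correlation of the pair.
#' @param params a [constraint_params()].
#' @return `NULL`, or a list with `sign` (+1/-1) and
#'   `directness` (`"direct"` or `"indirect"`).
#' @export
classify_path_constraint <- function(delta, r, params = constraint_params()) {
  if (delta > 0 && r > 0) {
    if (r >= params$beta) return(list(sign = 1L, directness = "direct"))
    if (r > params$alpha) return(list(sign = 1L, directness = "indirect"))
  } else if (delta < 0 && r < 0) {
    if (r <= -params$beta) return(list(sign = -1L, directness = "direct"))
    if (r < -params$alpha) return(list(sign = -1L, directness = "indirect"))
  }
  NULL
}

new_constraint_set <- function(df, genes) {
  rownames(df) <- NULL
  structure(df, genes = genes, class = c("constraint_set", "data.frame"))
}

#' Derive path-consistency constraints from a perturbation dataset
#'
#' For every mutated gene `k` and every other gene `l`, the coherency of the
#' pair is computed on each of `k`'s perturbation rows against its base
#' wild-type row. Pairs whose nonzero coherencies disagree in sign across
#' experiments are dropped (conservative: hard constraints must not
#' contradict each other); otherwise the shared sign is combined with the
#' pair's Pearson correlation over all experiments and classified by
#' [classify_path_constraint()].
#'
#' @param dataset an [expression_dataset()] with a Boolean matrix.
#' @param params a [constraint_params()].
#' @return A `constraint_set`: data frame with columns `source`, `target`
#'   (1-based gene indices), `sign` and `directness`, at most one row per
#'   ordered pair.
#' @export
derive_constraints <- function(dataset, params = constraint_params()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$bool)) stop("dataset carries no Boolean matrix")
  E <- dataset$bool
  ann <- dataset$annotations
  pert <- which(ann$ET != "WT")
  if (!length(pert)) stop("no perturbation experiments in the dataset")
  base <- base_wt_index(dataset)
  N <- length(dataset$genes)
  r_mat <- correlation_matrix(E)
  rows <- list()
  for (k in sort(unique(match(ann$MG[pert], dataset$genes)))) {
    krows <- pert[match(ann$MG[pert], dataset$genes) == k]
    for (l in seq_len(N)) {
      if (l == k) next
      dd <- vapply(krows, function(j) coherency(E[j, ], E[base[j], ], k, l),
                   integer(1))
      nz <- dd[dd != 0]
      if (!length(nz) || length(unique(sign(nz))) > 1) next
      cls <- classify_path_constraint(sign(nz[1]), r_mat[k, l], params)
      if (is.null(cls)) next
      rows[[length(rows) + 1]] <- data.frame(
        source = k, target = l, sign = cls$sign, directness = cls$directness,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(source = integer(0), target = integer(0),
                        sign = integer(0), directness = character(0),
                        stringsAsFactors = FALSE)
  new_constraint_set(df, dataset$genes)
}

# Signed reachability from `src`: 2 x N logical matrix, row 1 = reachable by
# a path (length >= 1) with positive sign product, row 2 = negative.
signed_reachability <- function(edges, N, src) {
  adj <- split(seq_len(nrow(edges)), factor(edges$from, levels = seq_len(N)))
  vis <- matrix(FALSE, 2, N)
  queue <- list()
  push <- function(node, pidx) {
    if (!vis[pidx, node]) {
      vis[pidx, node] <<- TRUE
      queue[[length(queue) + 1]] <<- c(node, pidx)
    }
  }
  for (j in adj[[src]]) push(edges$to[j], if (edges$sign[j] > 0) 1L else 2L)
  while (length(queue)) {
    st <- queue[[1]]; queue <- queue[-1]
    for (j in adj[[st[1]]]) {
      np <- if ((edges$sign[j] > 0) == (st[2] == 1L)) 1L else 2L
      push(edges$to[j], np)
    }
  }
  vis
}

#' Check a network against a constraint set
#'
#' A direct constraint `(k, l, sign)` holds iff the network's induced edge
#' set contains exactly that signed edge. An indirect constraint holds iff
#' some directed path `k -> ... -> l` of length >= 1 exists whose edge-sign
#' product equals the required sign (a direct edge of the right sign
#' counts: a weak correlation does not forbid directness).
#'
#' @param net a [boolean_network()].
#' @param constraints a `constraint_set` from [derive_constraints()] or
#'   [read_constraints()].
#' @return A list with `ok` (logical) and `violated` (the subset of
#'   constraint rows not satisfied).
#' @export
satisfies_constraints <- function(net, constraints) {
  stopifnot(inherits(net, "boolean_network"))
  N <- n_genes(net)
  if (nrow(constraints) == 0)
    return(list(ok = TRUE, violated = constraints[0, ]))
  if (any(constraints$source > N | constraints$target > N))
    stop("constraint gene index outside the network")
  edges <- network_edges(net)
  ekey <- paste(edges$from, edges$to, edges$sign)
  hold <- logical(nrow(constraints))
  reach_cache <- list()
  for (i in seq_len(nrow(constraints))) {
    k <- constraints$source[i]; l <- constraints$target[i]
    s <- constraints$sign[i]
    if (constraints$directness[i] == "direct") {
      hold[i] <- paste(k, l, s) %in% ekey
    } else {
      key <- as.character(k)
      if (is.null(reach_cache[[key]]))
        reach_cache[[key]] <- signed_reachability(edges, N, k)
      hold[i] <- reach_cache[[key]][if (s > 0) 1L else 2L, l]
    }
  }
  list(ok = all(hold), violated = constraints[!hold, , drop = FALSE])
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("Path-consistency constraints:", nrow(x), "(",
      sum(x$directness == "direct"), "direct,",
      sum(x$directness == "indirect"), "indirect )\n")
  if (nrow(x)) print(as.data.frame(x))
  invisible(x)
}
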