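#' Boolean network with nested canalyzing rules
#'
#' A Boolean network is a set of genes, each updated synchronously by one
#' [ncf_rule()]. The rule set induces a signed directed edge set: every
#' canalyzing tuple `(regulator, I, O)` in the rule of gene `i` contributes
#' an edge `regulator -> i` whose sign is `+1` when `I == O` (activation)
#' and `-1` otherwise (inhibition).
#'
#' @param genes character vector of gene names.
#' @param rules list of [ncf_rule()], one per gene, in gene order; rule
#'   `i` must have `target == i`.
#' @return An object of class `boolean_network`.
#' @export
boolean_network <- function(genes, rules) {
  genes <- as.character(genes)
  N <- length(genes)
  if (anyDuplicated(genes)) stop("gene names must be unique")
  if (length(rules) != N) stop("need exactly one rule per gene")
  for (i in seq_len(N)) {
    if (!inherits(rules[[i]], "ncf_rule")) stop("rules must be ncf_rule objects")
    if (rules[[i]]$target != i)
      stop("rule ", i, " targets gene ", rules[[i]]$target)
    if (any(rules[[i]]$regulators > N))
      stop("rule ", i, " references a regulator outside the gene set")
  }
  structure(list(genes = genes, rules = rules), class = "boolean_network")
}

n_genes <- function(net) length(net$genes)

#' Signed edge set induced by a network's rules
#'
#' @param net a [boolean_network()].
#' @return A data frame with columns `from`, `to` (1-based gene indices),
#'   `sign` (+1/-1) and `from_gene`, `to_gene` (names); one row per
#'   canalyzing tuple.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  from <- integer(0); to <- integer(0); sign <- integer(0)
  for (r in net$rules) {
    from <- c(from, r$regulators)
    to <- c(to, rep(r$target, length(r$regulators)))
    sign <- c(sign, tuple_sign(r$I, r$O))
  }
  data.frame(from = from, to = to, sign = sign,
             from_gene = net$genes[from], to_gene = net$genes[to],
             stringsAsFactors = FALSE)
}

# Normalize a clamp specification (named by gene or 1-based-index named
# integer vector / list) into parallel index/value integer vectors.
normalize_clamps <- function(net, clamps) {
  if (is.null(clamps) || length(clamps) == 0)
    return(list(gene = integer(0), val = integer(0)))
  vals <- as.integer(unlist(clamps))
  nm <- names(clamps)
  if (is.null(nm) || any(nm == ""))
    stop("clamps must be named by gene (name or index)")
  idx <- match(nm, net$genes)
  bad <- is.na(idx)
  idx[bad] <- suppressWarnings(as.integer(nm[bad]))
  if (any(is.na(idx)) || any(idx < 1 | idx > n_genes(net)))
    stop("unknown clamped gene: ", paste(nm[is.na(match(nm, net$genes))], collapse = ", "))
  if (!all(vals %in% 0:1)) stop("clamp values must be 0 or 1")
  list(gene = idx, val = vals)
}

# Flatten a network into the parallel-vector layout used by the C++ core.
flatten_network <- function(net) {
  rules <- net$rules
  list(nreg = vapply(rules, function(r) length(r$regulators), integer(1)),
       reg = unlist(lapply(rules, `[[`, "regulators"), use.names = FALSE),
       I = unlist(lapply(rules, `[[`, "I"), use.names = FALSE),
       O = unlist(lapply(rules, `[[`, "O"), use.names = FALSE),
       def = vapply(rules, `[[`, integer(1), "default_out"))
}

#' One synchronous update of all genes
#'
#' Every unclamped gene is set to the value of its rule evaluated on the
#' current state; clamped genes keep their clamp value regardless of rules.
#'
#' @param net a [boolean_network()].
#' @param state integer 0/1 state vector of length `N`.
#' @param clamps named integer vector of pinned values, e.g. `c(v1 = 0)`;
#'   names may be gene names or 1-based indices.
#' @return The next state (integer 0/1 vector).
#' @export
synchronous_step <- function(net, state, clamps = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  N <- n_genes(net)
  if (length(state) != N) stop("state length must equal the number of genes")
  cl <- normalize_clamps(net, clamps)
  out <- vapply(net$rules, evaluate_rule, integer(1), state = state)
  out[cl$gene] <- cl$val
  out
}

#' Simulate to an attractor
#'
#' Runs the deterministic synchronous trajectory from `initial` (with clamps
#' applied from the initial state onwards) and detects the first revisited
#' state. Returns the attractor cycle together with the transient length
#' `tau` (the minimal `t` with `v_t = v_{t+p}`) and the period `p`. If no
#' state is revisited within `max_steps` updates the final state is returned
#' as a period-1 pseudo-attractor with `truncated = TRUE`.
#'
#' @inheritParams synchronous_step
#' @param initial initial state vector.
#' @param max_steps maximum number of synchronous updates before truncation.
#' @return An object of class `bn_attractor`: list with `states` (period x N
#'   0/1 matrix, rows in cycle order starting at `v_tau`), `tau`, `period`
#'   and `truncated`.
#' @export
find_attractor <- function(net, initial, clamps = NULL, max_steps = 2000) {
  stopifnot(inherits(net, "boolean_network"), max_steps >= 1)
  N <- n_genes(net)
  if (length(initial) != N) stop("initial state length must equal the number of genes")
  if (!all(initial %in% 0:1)) stop("states are 0/1 vectors")
  cl <- normalize_clamps(net, clamps)
  fl <- flatten_network(net)
  res <- cpp_find_attractor(fl$nreg, fl$reg, fl$I, fl$O, fl$def,
                            as.integer(initial), cl$gene, cl$val,
                            as.integer(max_steps))
  colnames(res$states) <- net$genes
  structure(res, class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, ...) {
  kind <- if (x$truncated) "truncated trajectory (pseudo-attractor)"
          else if (x$period == 1L) "fixed point" else paste0("limit cycle (p=", x$period, ")")
  cat("Attractor:", kind, " tau =", x$tau, "\n")
  print(x$states)
  invisible(x)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network:", n_genes(x), "genes,", nrow(network_edges(x)),
      "signed edges\n")
  for (r in x$rules) {
    tup <- paste0("(", x$genes[r$regulators], ",", r$I, ",", r$O, ")",
                  collapse = "")
    cat(" ", x$genes[r$target], "=", paste0(tup, ":", r$default_out), "\n")
  }
  invisible(x)
}
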