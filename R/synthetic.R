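#' Benchmark specification
#'
#' Describes one synthetic benchmark: a scale-free Boolean network with
#' random nested canalyzing rules and the steady-state dataset obtained by
#' sampling wild-type attractors from random initial states and perturbing
#' every gene. Defaults mirror the artificial-data protocol: `2N - 3` edges,
#' 10000 random initial states, one knockout per gene.
#'
#' @param n_genes number of genes (N >= 3).
#' @param n_edges number of regulatory edges (default `2N - 3`).
#' @param n_initial_states random initial states used to sample wild-type
#'   attractors.
#' @param perturbations perturbation types applied to every gene: subset of
#'   `c("KO", "OE")`.
#' @param noise_sd standard deviation of the Gaussian noise added when
#'   exporting real-valued expression.
#' @param low,high real-valued expression levels (arbitrary units) that a
#'   0/1 bit maps to; defaults 2 and 8 are far enough apart for 2-means to
#'   separate them at any `noise_sd < 1.5`.
#' @param max_wt_attractors cap on exported wild-type rows (most frequent
#'   attractors first).
#' @param max_steps trajectory budget per simulation.
#' @param seed optional integer seed.
#' @export
benchmark_spec <- function(n_genes, n_edges = 2 * n_genes - 3,
                           n_initial_states = 10000,
                           perturbations = "KO", noise_sd = 0,
                           low = 2, high = 8, max_wt_attractors = 10,
                           max_steps = 2000, seed = NULL) {
  stopifnot(n_genes >= 3, n_edges >= n_genes - 1, n_initial_states >= 1,
            all(perturbations %in% c("KO", "OE")), noise_sd >= 0, low < high)
  structure(list(n_genes = as.integer(n_genes), n_edges = as.integer(n_edges),
                 n_initial_states = as.integer(n_initial_states),
                 perturbations = perturbations, noise_sd = noise_sd,
                 low = low, high = high,
                 max_wt_attractors = as.integer(max_wt_attractors),
                 max_steps = as.integer(max_steps),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate a scale-free Boolean network with random canalyzing rules
#'
#' Grows an undirected Barabasi-Albert graph (two seed nodes joined by one
#' edge; every further node attaches to two distinct existing nodes by
#' degree-preferential sampling, giving exactly `2N - 3` edges), orients
#' each edge uniformly at random, and assigns every gene a nested
#' canalyzing rule with uniform random canalyzing order and uniform random
#' canalyzing/canalyzed bits. A gene left without regulators receives one
#' incoming edge rewired from the highest-in-degree gene, so every rule has
#' at least one tuple.
#'
#' @param spec a [benchmark_spec()] (its `seed` is used if set), or an
#'   integer gene count.
#' @return A [boolean_network()].
#' @export
generate_ba_network <- function(spec) {
  if (is.numeric(spec)) spec <- benchmark_spec(spec)
  with_seed(spec$seed, generate_ba_network_impl(spec))
}

generate_ba_network_impl <- function(spec) {
  N <- spec$n_genes
  if (N < 3) stop("need at least 3 genes")
  a <- c(1L); b <- c(2L)  # undirected edge list
  for (j in 3:N) {
    deg <- tabulate(c(a, b), nbins = N)
    targets <- integer(0)
    while (length(targets) < 2) {
      cand <- sample.int(j - 1L, 1, prob = deg[seq_len(j - 1L)])
      if (!cand %in% targets) targets <- c(targets, cand)
    }
    a <- c(a, j, j); b <- c(b, targets)
  }
  flip <- runif(length(a)) < 0.5
  from <- ifelse(flip, b, a); to <- ifelse(flip, a, b)
  edges <- data.frame(from = as.integer(from), to = as.integer(to),
                      sign = sample(c(-1L, 1L), length(a), replace = TRUE),
                      fixed = FALSE)
  if (spec$n_edges < nrow(edges))
    stop("the growth scheme yields 2N - 3 edges; n_edges cannot be smaller")
  while (nrow(edges) < spec$n_edges) {  # optional densification beyond 2N - 3
    deg <- tabulate(c(edges$from, edges$to), nbins = N) + 1
    s <- sample.int(N, 1, prob = deg); t <- sample.int(N, 1, prob = deg)
    if (s == t || any(edges$from == s & edges$to == t)) next
    edges <- rbind(edges, data.frame(from = s, to = t,
                                     sign = sample(c(-1L, 1L), 1), fixed = FALSE))
  }
  # rewire so every gene has a regulator
  for (g in which(tabulate(edges$to, nbins = N) == 0)) {
    for (h in order(-tabulate(edges$to, nbins = N))) {
      if (sum(edges$to == h) < 2) stop("rewiring failed")  # unreachable: 2N-3 edges
      cand <- which(edges$to == h & edges$from != g)
      cand <- cand[!vapply(edges$from[cand],
                           function(s) any(edges$from == s & edges$to == g),
                           logical(1))]
      if (length(cand)) { edges$to[sample_one(cand)] <- g; break }
    }
  }
  topology_to_chromosome(edges, paste0("v", seq_len(N)))$network
}

majority_vector <- function(states) {
  as.integer(2 * colSums(states) >= nrow(states))  # ties break to 1
}

#' Generate a steady-state dataset from a network
#'
#' Wild-type attractors are sampled by simulating from
#' `spec$n_initial_states` uniform random initial states; one row is
#' exported per distinct attractor (most frequent first, capped at
#' `spec$max_wt_attractors`), collapsing limit cycles to per-gene majority
#' votes (ties to 1). Each gene is then perturbed (knocked out and/or
#' overexpressed, clamped for the whole trajectory) starting from the most
#' frequent wild-type attractor's exported state, and the resulting
#' attractor becomes a perturbation row annotated with the mutated gene and
#' its base wild-type row. With `spec$noise_sd`/`low`/`high` a real-valued
#' matrix is exported alongside, mapping bit `b` to
#' `Normal(b*high + (1-b)*low, noise_sd)`.
#'
#' @param net a [boolean_network()].
#' @param spec a [benchmark_spec()].
#' @return An [expression_dataset()] with Boolean and real matrices; the
#'   attribute `attractor_periods` records each row's attractor period and
#'   truncation flag.
#' @export
generate_dataset <- function(net, spec) {
  stopifnot(inherits(net, "boolean_network"), inherits(spec, "benchmark_spec"))
  with_seed(spec$seed, generate_dataset_impl(net, spec))
}

generate_dataset_impl <- function(net, spec) {
  N <- n_genes(net)
  fl <- flatten_network(net)
  inits <- matrix(sample(0:1, spec$n_initial_states * N, replace = TRUE),
                  nrow = spec$n_initial_states)
  wt <- cpp_collect_attractors(fl$nreg, fl$reg, fl$I, fl$O, fl$def, inits,
                               integer(0), integer(0), spec$max_steps)
  ord <- order(-wt$counts)
  keep <- head(ord, spec$max_wt_attractors)
  wt_rows <- t(vapply(wt$states[keep], majority_vector, integer(N)))
  wt_ids <- sprintf("WT%02d", seq_along(keep))
  periods <- data.frame(period = vapply(wt$states[keep], nrow, integer(1)),
                        truncated = wt$truncated[keep])
  rows <- wt_rows
  ann <- data.frame(id = wt_ids, MG = NA_character_, ET = "WT",
                    WT = NA_character_, stringsAsFactors = FALSE)
  base_state <- wt_rows[1, ]
  counter <- c(KO = 0L, OE = 0L)
  for (g in seq_len(N)) {
    for (ptype in spec$perturbations) {
      att <- cpp_find_attractor(fl$nreg, fl$reg, fl$I, fl$O, fl$def,
                                base_state, g, if (ptype == "KO") 0L else 1L,
                                spec$max_steps)
      counter[ptype] <- counter[ptype] + 1L
      rows <- rbind(rows, majority_vector(att$states))
      ann <- rbind(ann, data.frame(id = sprintf("%s%02d", ptype, counter[ptype]),
                                   MG = net$genes[g], ET = ptype, WT = wt_ids[1],
                                   stringsAsFactors = FALSE))
      periods <- rbind(periods, data.frame(period = att$period,
                                           truncated = att$truncated))
    }
  }
  real <- rows * spec$high + (1 - rows) * spec$low +
    matrix(rnorm(length(rows), sd = spec$noise_sd), nrow = nrow(rows))
  ds <- expression_dataset(net$genes, ann, bool = rows, real = real)
  attr(ds, "attractor_periods") <- periods
  ds
}

#' Generate a full benchmark (network + dataset)
#'
#' @param spec a [benchmark_spec()].
#' @return List with `network` (the gold standard) and `dataset`.
#' @export
generate_benchmark <- function(spec) {
  with_seed(spec$seed, {
    net <- generate_ba_network_impl(spec)
    list(network = net, dataset = generate_dataset_impl(net, spec))
  })
}
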