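#' Genetic algorithm configuration
#'
#' Defaults follow the published study conditions: a population of 200
#' networks, 2 elites, termination after 200 generations without strict
#' improvement of the best fitness, and a mutation-gene choice that skips
#' genes whose per-gene similarity has stayed within a 2% band over the
#' last 100 generations.
#'
#' @param population_size number of chromosomes per generation.
#' @param n_elites networks copied unchanged into the next generation.
#' @param stop_stagnant_generations stop after this many generations
#'   without strict improvement of the best fitness (ties do not reset).
#' @param gene_convergence_window generations over which a gene's average
#'   similarity must move to stay eligible for mutation.
#' @param gene_convergence_tolerance the movement band (fraction).
#' @param max_generations hard cap on generations.
#' @param mutation_retry_cap constraint-violating offspring discarded before
#'   giving up and returning an unmodified parent copy.
#' @param structure_fixed restrict mutations so the signed edge set never
#'   changes (the rule-search mode used to fit update functions to a fixed
#'   topology); disables removal/insertion and, unless
#'   `structure_fixed_allow_sign_flips`, also the sign-changing single flips.
#' @param structure_fixed_allow_sign_flips permit canalyzing/canalyzed
#'   single flips in `structure_fixed` mode (preserves the unsigned edge set
#'   only).
#' @param lineage_history track each chromosome's own per-gene similarity
#'   history (default); `FALSE` tracks the population best instead.
#' @param stop_on_perfect stop as soon as the best fitness reaches 1 (it
#'   cannot improve further, so the stagnation countdown is redundant).
#' @param seed integer seed for the whole run (`NULL` uses the current RNG).
#' @param n_workers parallel workers for fitness evaluation (fork-based;
#'   results are identical to sequential evaluation).
#' @param max_steps trajectory budget per attractor simulation.
#' @export
ga_config <- function(population_size = 200, n_elites = 2,
                      stop_stagnant_generations = 200,
                      gene_convergence_window = 100,
                      gene_convergence_tolerance = 0.02,
                      max_generations = 5000, mutation_retry_cap = 100,
                      structure_fixed = FALSE,
                      structure_fixed_allow_sign_flips = FALSE,
                      lineage_history = TRUE, stop_on_perfect = TRUE,
                      seed = NULL, n_workers = 1, max_steps = 2000) {
  stopifnot(population_size >= 2, n_elites >= 0, n_elites < population_size,
            gene_convergence_tolerance >= 0, gene_convergence_tolerance <= 1,
            stop_stagnant_generations >= 1, max_generations >= 1,
            mutation_retry_cap >= 1, n_workers >= 1)
  structure(list(population_size = as.integer(population_size),
                 n_elites = as.integer(n_elites),
                 stop_stagnant_generations = as.integer(stop_stagnant_generations),
                 gene_convergence_window = as.integer(gene_convergence_window),
                 gene_convergence_tolerance = gene_convergence_tolerance,
                 max_generations = as.integer(max_generations),
                 mutation_retry_cap = as.integer(mutation_retry_cap),
                 structure_fixed = isTRUE(structure_fixed),
                 structure_fixed_allow_sign_flips = isTRUE(structure_fixed_allow_sign_flips),
                 lineage_history = isTRUE(lineage_history),
                 stop_on_perfect = isTRUE(stop_on_perfect),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 n_workers = as.integer(n_workers),
                 max_steps = as.integer(max_steps)),
            class = "ga_config")
}

sample_one <- function(x) x[sample.int(length(x), 1L)]

new_chromosome <- function(network, fps) {
  structure(list(network = network, fps = fps, fitness = NA_real_,
                 per_gene = NULL, history = NULL),
            class = "ga_chromosome")
}

mutation_kinds <- c("canalyzing_flip", "canalyzed_flip", "both_flip",
                    "swap", "removal", "insertion")

active_kinds <- function(config) {
  if (!config$structure_fixed) return(mutation_kinds)
  if (config$structure_fixed_allow_sign_flips)
    c("canalyzing_flip", "canalyzed_flip", "both_flip", "swap")
  else c("both_flip", "swap")
}

# ---- population initialization -------------------------------------------

# Signed topology satisfying all constraints: direct-constraint edges are
# seeded (and later protected as FPS tuples), the edge count is filled to at
# least 2N-3 by degree-preferential attachment, and indirect constraints are
# repaired greedily by adding a direct edge or a signed two-hop path.
build_feasible_topology <- function(constraints, N, min_edges) {
  direct <- constraints[constraints$directness == "direct", , drop = FALSE]
  if (nrow(direct) && anyDuplicated(direct[c("source", "target")]))
    stop("contradictory direct constraints: a pair admits only one signed edge")
  edges <- data.frame(from = direct$source, to = direct$target,
                      sign = direct$sign,
                      fixed = rep(TRUE, nrow(direct)))
  has_edge <- function(a, b) any(edges$from == a & edges$to == b)
  add_edge <- function(a, b, s, fixed = FALSE)
    edges <<- rbind(edges, data.frame(from = a, to = b, sign = s, fixed = fixed))
  # preferential-attachment fill
  tries <- 0L
  while (nrow(edges) < min_edges && tries < 200L * N) {
    deg <- tabulate(c(edges$from, edges$to), nbins = N) + 1
    s <- sample.int(N, 1, prob = deg)
    t <- sample.int(N, 1, prob = deg)
    tries <- tries + 1L
    if (s == t || has_edge(s, t)) next
    add_edge(s, t, sample(c(-1L, 1L), 1))
  }
  if (nrow(edges) < min_edges)
    stop("could not assemble a topology with the requested edge count")
  # indirect-constraint repair
  indirect <- constraints[constraints$directness == "indirect", , drop = FALSE]
  for (i in seq_len(nrow(indirect))) {
    k <- indirect$source[i]; l <- indirect$target[i]; s <- indirect$sign[i]
    if (signed_reachability(edges, N, k)[if (s > 0) 1L else 2L, l]) next
    if (!has_edge(k, l)) { add_edge(k, l, s); next }
    ok <- FALSE
    for (m in sample(setdiff(seq_len(N), c(k, l)))) {
      s1 <- if (has_edge(k, m)) edges$sign[edges$from == k & edges$to == m][1] else NA
      s2 <- if (has_edge(m, l)) edges$sign[edges$from == m & edges$to == l][1] else NA
      want2 <- if (is.na(s1)) NA else s * s1
      if (!is.na(s1) && !is.na(s2) && s1 * s2 == s) { ok <- TRUE; break }
      if (!is.na(s1) && is.na(s2)) { add_edge(m, l, want2); ok <- TRUE; break }
      if (is.na(s1) && is.na(s2)) {
        s1 <- sample(c(-1L, 1L), 1)
        add_edge(k, m, s1); add_edge(m, l, s * s1); ok <- TRUE; break
      }
      if (is.na(s1) && !is.na(s2)) { add_edge(k, m, s * s2); ok <- TRUE; break }
    }
    if (!ok) stop("could not satisfy indirect constraint ", k, " -> ", l)
  }
  # every gene must have at least one regulator
  indeg <- tabulate(edges$to, nbins = N)
  for (g in which(indeg == 0)) {
    done <- FALSE
    for (h in order(-tabulate(edges$to, nbins = N))) {
      if (sum(edges$to == h) < 2) break
      cand <- which(edges$to == h & !edges$fixed & edges$from != g)
      cand <- cand[!vapply(edges$from[cand], has_edge, logical(1), b = g)]
      if (length(cand)) {
        edges$to[sample_one(cand)] <- g
        done <- TRUE
        break
      }
    }
    if (!done) {
      src <- sample_one(setdiff(seq_len(N), g))
      if (!has_edge(src, g)) add_edge(src, g, sample(c(-1L, 1L), 1))
      else stop("could not guarantee a regulator for gene ", g)
    }
  }
  edges
}

topology_to_chromosome <- function(edges, genes) {
  N <- length(genes)
  rules <- vector("list", N)
  fps <- vector("list", N)
  for (i in seq_len(N)) {
    inc <- which(edges$to == i)
    inc <- inc[sample.int(length(inc))]  # random canalyzing order
    I <- sample(0:1, length(inc), replace = TRUE)
    O <- ifelse(edges$sign[inc] > 0, I, 1L - I)
    rules[[i]] <- ncf_rule(i, edges$from[inc], I, O)
    fps[[i]] <- edges$fixed[inc]
  }
  new_chromosome(boolean_network(genes, rules), fps)
}

#' Initialize a feasible GA population
#'
#' Builds `population_size` random networks whose topologies satisfy the
#' constraint set: all direct-constraint edges are present with the right
#' sign (marked as fixed-path tuples, protected from structural mutation),
#' the edge count is filled to at least `2N - 3` by degree-preferential
#' attachment, and indirect constraints are repaired by greedy signed-path
#' insertion. Canalyzing orders and unconstrained canalyzing/canalyzed
#' values are uniform random.
#'
#' @param constraints a `constraint_set` (may have zero rows).
#' @param N number of genes.
#' @param config a [ga_config()].
#' @param genes optional gene names (defaults to `v1..vN`).
#' @return List of `ga_chromosome` objects, each passing
#'   [satisfies_constraints()].
#' @export
initialize_population <- function(constraints, N, config = ga_config(),
                                  genes = NULL) {
  genes <- genes %||% attr(constraints, "genes") %||% paste0("v", seq_len(N))
  stopifnot(length(genes) == N)
  min_edges <- 2L * N - 3L
  lapply(seq_len(config$population_size), function(j) {
    for (attempt in 1:20) {
      chrom <- topology_to_chromosome(
        build_feasible_topology(constraints, N, min_edges), genes)
      if (satisfies_constraints(chrom$network, constraints)$ok) return(chrom)
    }
    stop("failed to build a feasible chromosome after 20 attempts")
  })
}

# ---- selection ------------------------------------------------------------

roulette_index <- function(fitnesses) {
  if (all(fitnesses <= 0)) return(sample.int(length(fitnesses), 1))
  sample.int(length(fitnesses), 1, prob = fitnesses)
}

#' Roulette-wheel parent selection
#'
#' Picks one chromosome with probability proportional to its cached fitness
#' (uniform when every fitness is zero).
#'
#' @param population list of evaluated `ga_chromosome`s.
#' @export
roulette_select <- function(population) {
  fits <- vapply(population, `[[`, numeric(1), "fitness")
  if (anyNA(fits)) stop("population fitness must be evaluated before selection")
  population[[roulette_index(fits)]]
}

# ---- mutation -------------------------------------------------------------

#' Choose the gene whose rule will be mutated
#'
#' First tier: genes whose average per-gene similarity is imperfect and has
#' moved more than the convergence tolerance over the last
#' `gene_convergence_window` generations (genes with shorter histories are
#' treated as unconverged). Fallbacks: any imperfect gene, then any gene.
#'
#' @param chromosome an evaluated `ga_chromosome`.
#' @param config a [ga_config()].
#' @param history optional similarity-history matrix to use instead of the
#'   chromosome's own lineage history (population-best tracking).
#' @return A 1-based gene index.
#' @export
choose_mutation_gene <- function(chromosome, config = ga_config(),
                                 history = NULL) {
  N <- n_genes(chromosome$network)
  sbar <- chromosome$per_gene
  if (is.null(sbar)) return(sample.int(N, 1))
  hist <- history %||% chromosome$history
  imperfect <- which(sbar < 1 - 1e-12)
  if (!length(imperfect)) return(sample.int(N, 1))
  w <- config$gene_convergence_window
  converged <- rep(FALSE, N)
  if (!is.null(hist) && nrow(hist) >= w) {
    recent <- hist[(nrow(hist) - w + 1):nrow(hist), , drop = FALSE]
    rng <- apply(recent, 2, function(col) max(col) - min(col))
    converged <- rng <= config$gene_convergence_tolerance
  }
  tier1 <- imperfect[!converged[imperfect]]
  if (length(tier1)) sample_one(tier1) else sample_one(imperfect)
}

#' Apply one rule mutation of a given kind
#'
#' The six kinds act on the rule of gene `k`:
#' * `canalyzing_flip` — flip `I` of a random variable-path (VPS) tuple
#'   (switches the interaction sign);
#' * `canalyzed_flip` — flip `O` of a random VPS tuple (switches the sign
#'   and toggles conjunction/disjunction semantics);
#' * `both_flip` — flip both bits of any tuple (sign preserved);
#' * `swap` — exchange the cascade positions of two tuples within the same
#'   subgroup (both FPS or both VPS);
#' * `removal` — delete a random VPS tuple (the rule keeps >= 1 tuple);
#' * `insertion` — insert a new random tuple for a regulator `v` not already
#'   in the rule, `v != k`, with `|r(v, k)| > alpha`, at the head of the VPS
#'   part.
#'
#' The default output is re-derived as the complement of the last canalyzed
#' value. Returns `NULL` when the kind is inapplicable (no eligible tuple or
#' candidate regulator), so callers can resample another kind.
#'
#' @param chromosome a `ga_chromosome`.
#' @param k gene index whose rule is mutated.
#' @param kind one of `"canalyzing_flip"`, `"canalyzed_flip"`,
#'   `"both_flip"`, `"swap"`, `"removal"`, `"insertion"`.
#' @param correlations gene correlation matrix (needed for `insertion`).
#' @param params a [constraint_params()] (its `alpha` gates insertion).
#' @return A new (not yet feasibility-checked) chromosome, or `NULL`.
#' @export
mutate_rule <- function(chromosome, k, kind, correlations = NULL,
                        params = constraint_params()) {
  kind <- match.arg(kind, mutation_kinds)
  rule <- chromosome$network$rules[[k]]
  fps <- chromosome$fps[[k]]
  m <- length(rule$regulators)
  vps_idx <- which(!fps)
  reg <- rule$regulators; I <- rule$I; O <- rule$O
  if (kind == "canalyzing_flip") {
    if (!length(vps_idx)) return(NULL)
    j <- sample_one(vps_idx); I[j] <- 1L - I[j]
  } else if (kind == "canalyzed_flip") {
    if (!length(vps_idx)) return(NULL)
    j <- sample_one(vps_idx); O[j] <- 1L - O[j]
  } else if (kind == "both_flip") {
    j <- sample.int(m, 1); I[j] <- 1L - I[j]; O[j] <- 1L - O[j]
  } else if (kind == "swap") {
    groups <- list(which(fps), vps_idx)
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (!length(groups)) return(NULL)
    g <- groups[[sample.int(length(groups), 1)]]
    jj <- g[sample.int(length(g), 2)]
    perm <- seq_len(m); perm[jj] <- rev(jj)
    reg <- reg[perm]; I <- I[perm]; O <- O[perm]; fps <- fps[perm]
  } else if (kind == "removal") {
    if (!length(vps_idx) || m < 2) return(NULL)
    j <- sample_one(vps_idx)
    reg <- reg[-j]; I <- I[-j]; O <- O[-j]; fps <- fps[-j]
  } else if (kind == "insertion") {
    if (is.null(correlations)) stop("insertion needs the correlation matrix")
    cand <- setdiff(which(abs(correlations[, k]) > params$alpha), c(k, reg))
    if (!length(cand)) return(NULL)
    v <- sample_one(cand)
    pos <- if (length(vps_idx)) min(vps_idx) else m + 1L
    ins <- function(x, val) append(x, val, after = pos - 1L)
    reg <- ins(reg, v)
    I <- ins(I, sample(0:1, 1)); O <- ins(O, sample(0:1, 1))
    fps <- ins(fps, FALSE)
  }
  chromosome$network$rules[[k]] <- ncf_rule(k, reg, I, O)
  chromosome$fps[[k]] <- fps
  chromosome$fitness <- NA_real_
  chromosome$per_gene <- NULL
  chromosome
}

#' Produce one feasible offspring from a parent
#'
#' Repeats (choose mutation gene, choose kind uniformly, apply) until the
#' mutated network satisfies the constraint set. Kinds found inapplicable
#' are resampled without counting against the retry cap; constraint-
#' violating offspring do count. After `mutation_retry_cap` failures an
#' unmodified parent copy is returned with attribute `retry_failed = TRUE`.
#'
#' @inheritParams mutate_rule
#' @param parent a feasible, evaluated `ga_chromosome`.
#' @param constraints the `constraint_set` the offspring must satisfy.
#' @param config a [ga_config()] (kind pool respects `structure_fixed`).
#' @param history forwarded to [choose_mutation_gene()].
#' @export
propose_offspring <- function(parent, constraints, correlations,
                              config = ga_config(),
                              params = constraint_params(), history = NULL) {
  kinds <- active_kinds(config)
  attempts <- 0L
  repeat {
    k <- choose_mutation_gene(parent, config, history)
    off <- NULL
    tried <- character(0)
    repeat {
      avail <- setdiff(kinds, tried)
      if (!length(avail)) break
      kind <- sample_one(avail)
      off <- mutate_rule(parent, k, kind, correlations, params)
      if (!is.null(off)) break
      tried <- c(tried, kind)
    }
    if (!is.null(off) && satisfies_constraints(off$network, constraints)$ok)
      return(off)
    attempts <- attempts + 1L
    if (attempts >= config$mutation_retry_cap) {
      off <- parent
      attr(off, "retry_failed") <- TRUE
      return(off)
    }
  }
}

# ---- main loop ------------------------------------------------------------

evaluate_fitness <- function(chrom, dataset, max_steps) {
  rep <- dynamics_accuracy(chrom$network, dataset, max_steps = max_steps)
  chrom$fitness <- rep$dynamics_accuracy
  chrom$per_gene <- unname(rep$per_gene)
  chrom
}

#' Run the constrained genetic algorithm
#'
#' Generational loop: evaluate the dynamics accuracy of every chromosome
#' (optionally across parallel workers; evaluation is read-only so results
#' are identical to sequential evaluation), carry the `n_elites` best
#' unchanged, and rebuild the rest of the population from roulette-selected
#' parents via [propose_offspring()]. There is no crossover. The run stops
#' when the best fitness has not strictly improved for
#' `stop_stagnant_generations` generations, when it reaches 1 (if
#' `stop_on_perfect`), or at `max_generations`.
#'
#' @param dataset an [expression_dataset()] with a Boolean matrix.
#' @param constraints a `constraint_set` (derive with
#'   [derive_constraints()]).
#' @param config a [ga_config()].
#' @param params a [constraint_params()]; only `alpha` is used (insertion
#'   gate).
#' @return A `ga_result`: list with `network` (best-ever network), `best`
#'   (its chromosome), `fitness`, `log` (per-generation data frame with
#'   best/mean fitness and feasibility rate), `generations` and
#'   `retry_failures`.
#' @export
evolve <- function(dataset, constraints, config = ga_config(),
                   params = constraint_params()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$bool)) stop("dataset must be binarized first")
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- length(dataset$genes)
  corr <- correlation_matrix(dataset$bool)
  pop <- initialize_population(constraints, N, config, genes = dataset$genes)
  window <- config$gene_convergence_window
  best_ever <- NULL
  best_fit <- -Inf
  stagnant <- 0L
  retry_failures <- 0L
  best_hist <- NULL
  log_rows <- vector("list", config$max_generations)
  gen <- 0L
  repeat {
    gen <- gen + 1L
    todo <- which(vapply(pop, function(c) is.na(c$fitness), logical(1)))
    if (length(todo)) {
      evals <- if (config$n_workers > 1)
        parallel::mclapply(pop[todo], evaluate_fitness, dataset = dataset,
                           max_steps = config$max_steps,
                           mc.cores = config$n_workers)
      else lapply(pop[todo], evaluate_fitness, dataset = dataset,
                  max_steps = config$max_steps)
      pop[todo] <- evals
    }
    pop <- lapply(pop, function(c) {
      c$history <- rbind(c$history, c$per_gene)
      if (nrow(c$history) > window)
        c$history <- c$history[(nrow(c$history) - window + 1):nrow(c$history), ,
                               drop = FALSE]
      c
    })
    fits <- vapply(pop, `[[`, numeric(1), "fitness")
    ord <- order(-fits)
    gen_best <- fits[ord[1]]
    if (gen_best > best_fit) {
      best_fit <- gen_best
      best_ever <- pop[[ord[1]]]
      stagnant <- 0L
    } else stagnant <- stagnant + 1L
    best_hist <- rbind(best_hist, pop[[ord[1]]]$per_gene)
    if (!is.null(best_hist) && nrow(best_hist) > window)
      best_hist <- best_hist[(nrow(best_hist) - window + 1):nrow(best_hist), ,
                             drop = FALSE]
    feas <- mean(vapply(pop, function(c)
      satisfies_constraints(c$network, constraints)$ok, logical(1)))
    log_rows[[gen]] <- data.frame(generation = gen, best_fitness = best_fit,
                                  generation_best = gen_best,
                                  mean_fitness = mean(fits),
                                  feasibility_rate = feas)
    if ((config$stop_on_perfect && best_fit >= 1 - 1e-12) ||
        stagnant >= config$stop_stagnant_generations ||
        gen >= config$max_generations) break
    elites <- pop[ord[seq_len(config$n_elites)]]
    n_off <- config$population_size - config$n_elites
    offspring <- vector("list", n_off)
    hist_arg <- if (config$lineage_history) NULL else best_hist
    for (j in seq_len(n_off)) {
      parent <- pop[[roulette_index(fits)]]
      off <- propose_offspring(parent, constraints, corr, config, params,
                               history = hist_arg)
      if (isTRUE(attr(off, "retry_failed"))) {
        retry_failures <- retry_failures + 1L
        attr(off, "retry_failed") <- NULL
      }
      offspring[[j]] <- off
    }
    pop <- c(elites, offspring)
  }
  structure(list(network = best_ever$network, best = best_ever,
                 fitness = best_fit,
                 log = do.call(rbind, log_rows[seq_len(gen)]),
                 generations = gen, retry_failures = retry_failures,
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA result: best dynamics accuracy %.4f after %d generations\n",
              x$fitness, x$generations))
  invisible(x)
}

#' One-call inference pipeline
#'
#' Binarizes the dataset if needed, derives the path-consistency
#' constraints, and runs [evolve()].
#'
#' @inheritParams evolve
#' @return List with `result` (a `ga_result`), `constraints` and the
#'   (binarized) `dataset`.
#' @export
infer_network <- function(dataset, params = constraint_params(),
                          config = ga_config()) {
  if (is.null(dataset$bool)) dataset <- binarize(dataset, seed = config$seed)
  constraints <- derive_constraints(dataset, params)
  res <- evolve(dataset, constraints, config, params)
  list(result = res, constraints = constraints, dataset = dataset)
}
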