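# Small shared fixtures: a 10-gene benchmark with derived constraints, and
# an evaluated chromosome to mutate.
ga_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bm <- generate_benchmark(benchmark_spec(10, n_initial_states = 500,
                                              seed = 77))
      cs <- derive_constraints(bm$dataset)
      corr <- suppressWarnings(stats::cor(bm$dataset$bool))
      corr[is.na(corr)] <- 0
      cache <<- list(bm = bm, cs = cs, corr = corr)
    }
    cache
  }
})

evaluated_chromosome <- function(fx, seed = 1) {
  set.seed(seed)
  chrom <- initialize_population(fx$cs, 10, ga_config(population_size = 2, n_elites = 0),
                                 genes = fx$bm$dataset$genes)[[1]]
  rep <- dynamics_accuracy(chrom$network, fx$bm$dataset)
  chrom$fitness <- rep$dynamics_accuracy
  chrom$per_gene <- unname(rep$per_gene)
  chrom
}

new_chrom_1tuple <- function() {
  net <- boolean_network(c("v1", "v2", "v3"),
                         list(ncf_rule(1, 2, 1, 1), ncf_rule(2, 1, 1, 1),
                              ncf_rule(3, 1, 0, 1)))
  structure(list(network = net, fps = list(FALSE, FALSE, FALSE),
                 fitness = 0.5, per_gene = c(1, 0.5, 1), history = NULL),
            class = "ga_chromosome")
}

test_that("initial populations are feasible and sized 2N-3 without constraints", {
  set.seed(81)
  empty <- structure(data.frame(source = integer(0), target = integer(0),
                                sign = integer(0), directness = character(0)),
                     genes = paste0("v", 1:10),
                     class = c("constraint_set", "data.frame"))
  pop <- initialize_population(empty, 10, ga_config(population_size = 30))
  expect_length(pop, 30)
  for (c in pop) {
    e <- network_edges(c$network)
    expect_identical(nrow(e), 17L)
    expect_true(all(tabulate(e$to, nbins = 10) >= 1))
    expect_true(all(!unlist(c$fps)))
  }
})

test_that("direct-constraint edges are seeded in every chromosome as FPS tuples", {
  fx <- ga_fixture()
  set.seed(82)
  pop <- initialize_population(fx$cs, 10, ga_config(population_size = 20),
                               genes = fx$bm$dataset$genes)
  direct <- fx$cs[fx$cs$directness == "direct", ]
  expect_gt(nrow(direct), 0)
  for (c in pop) {
    expect_true(satisfies_constraints(c$network, fx$cs)$ok)
    e <- network_edges(c$network)
    for (i in seq_len(nrow(direct))) {
      expect_true(any(e$from == direct$source[i] & e$to == direct$target[i] &
                      e$sign == direct$sign[i]))
      # and the corresponding tuple is protected
      rule <- c$network$rules[[direct$target[i]]]
      j <- which(rule$regulators == direct$source[i])
      expect_true(c$fps[[direct$target[i]]][j])
    }
  }
})

test_that("contradictory direct constraints abort initialization", {
  bad <- structure(data.frame(source = c(1L, 1L), target = c(2L, 2L),
                              sign = c(1L, -1L),
                              directness = c("direct", "direct")),
                   genes = paste0("v", 1:5),
                   class = c("constraint_set", "data.frame"))
  expect_error(initialize_population(bad, 5, ga_config(population_size = 2, n_elites = 0)),
               "contradictory")
})

test_that("roulette selection frequencies are fitness-proportional", {
  set.seed(83)
  # fitness vector (0.25, 0.75): expected pick rates 0.25 / 0.75
  n <- 1e5
  draws <- vapply(seq_len(n), function(i) roulette_index(c(0.25, 0.75)),
                  integer(1))
  p <- mean(draws == 2)
  sigma <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p - 0.75), 3 * sigma)
  # equal fitnesses: uniform
  draws2 <- vapply(seq_len(n), function(i) roulette_index(rep(1, 4)), integer(1))
  expect_lt(max(abs(tabulate(draws2, 4) / n - 0.25)),
            3 * sqrt(0.25 * 0.75 / n))
  # all-zero fitnesses fall back to uniform
  draws3 <- vapply(seq_len(2e4), function(i) roulette_index(c(0, 0)), integer(1))
  expect_lt(abs(mean(draws3 == 1) - 0.5), 3 * sqrt(0.25 / 2e4))
})

test_that("mutation-gene choice targets imperfect, unconverged genes", {
  fx <- ga_fixture()
  chrom <- evaluated_chromosome(fx)
  cfg <- ga_config(gene_convergence_window = 5, gene_convergence_tolerance = 0.02)
  # single imperfect gene is always chosen
  chrom$per_gene <- c(1, 1, 0.7, 1, 1, 1, 1, 1, 1, 1)
  chrom$history <- NULL
  expect_true(all(vapply(1:20, function(i) choose_mutation_gene(chrom, cfg),
                         integer(1)) == 3L))
  # a flat (converged) imperfect gene is excluded once another is eligible
  chrom$per_gene <- c(1, 1, 0.7, 0.9, 1, 1, 1, 1, 1, 1)
  flat <- matrix(rep(chrom$per_gene, 5), nrow = 5, byrow = TRUE)
  moving <- flat; moving[, 4] <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  chrom$history <- moving
  expect_true(all(vapply(1:20, function(i) choose_mutation_gene(chrom, cfg),
                         integer(1)) == 4L))
  # all genes perfect: uniform over all genes
  chrom$per_gene <- rep(1, 10)
  picks <- vapply(1:50, function(i) choose_mutation_gene(chrom, cfg), integer(1))
  expect_gt(length(unique(picks)), 3)
})

test_that("the six mutation kinds transform tuples as documented", {
  fx <- ga_fixture()
  set.seed(84)
  chrom <- evaluated_chromosome(fx)
  pick_gene <- function(min_tuples = 1)
    which(vapply(chrom$network$rules,
                 function(r) length(r$regulators), integer(1)) >= min_tuples)[1]

  k <- pick_gene(2)
  old <- chrom$network$rules[[k]]

  m1 <- mutate_rule(chrom, k, "canalyzing_flip", fx$corr)
  if (!is.null(m1)) {
    r1 <- m1$network$rules[[k]]
    j <- which(r1$I != old$I)
    expect_length(j, 1)
    expect_identical(r1$O, old$O[seq_along(r1$O)])
    expect_false(chrom$fps[[k]][j])  # VPS only
  }

  m3 <- mutate_rule(chrom, k, "both_flip", fx$corr)
  r3 <- m3$network$rules[[k]]
  j3 <- which(r3$I != old$I)
  expect_length(j3, 1)
  expect_identical(r3$O[j3], 1L - old$O[j3])
  # sign preserved everywhere
  expect_identical(ifelse(r3$I == r3$O, 1L, -1L),
                   ifelse(old$I == old$O, 1L, -1L))

  m4 <- mutate_rule(chrom, k, "swap", fx$corr)
  if (!is.null(m4)) {
    r4 <- m4$network$rules[[k]]
    expect_setequal(r4$regulators, old$regulators)
    expect_false(identical(r4$regulators, old$regulators))
    # tuples travel with their bits
    for (v in r4$regulators) {
      expect_identical(r4$I[r4$regulators == v], old$I[old$regulators == v])
      expect_identical(r4$O[r4$regulators == v], old$O[old$regulators == v])
    }
  }

  m5 <- mutate_rule(chrom, k, "removal", fx$corr)
  if (!is.null(m5)) {
    r5 <- m5$network$rules[[k]]
    expect_identical(length(r5$regulators), length(old$regulators) - 1L)
    expect_true(all(r5$regulators %in% old$regulators))
  }

  m6 <- mutate_rule(chrom, k, "insertion", fx$corr)
  if (!is.null(m6)) {
    r6 <- m6$network$rules[[k]]
    expect_identical(length(r6$regulators), length(old$regulators) + 1L)
    v <- setdiff(r6$regulators, old$regulators)
    expect_length(v, 1)
    expect_gt(abs(fx$corr[v, k]), 0.1)
    expect_false(v == k)
    # inserted at the head of the VPS part
    vps_pos <- which(!m6$fps[[k]])
    expect_identical(r6$regulators[vps_pos[1]], v)
  }

  # defaults always re-derived from the last canalyzed value
  for (m in list(m3, m4, m5, m6)) {
    if (is.null(m)) next
    r <- m$network$rules[[k]]
    expect_identical(r$default_out, 1L - r$O[length(r$O)])
  }
})

test_that("inapplicable mutation kinds signal NULL", {
  chrom <- new_chrom_1tuple()
  expect_null(mutate_rule(chrom, 2, "removal"))      # single-tuple rule
  expect_null(mutate_rule(chrom, 2, "swap"))         # nothing to swap
  # every candidate regulator below the correlation floor blocks insertion
  corr0 <- matrix(0, 3, 3); diag(corr0) <- 1
  expect_null(mutate_rule(chrom, 2, "insertion", corr0))
  # all tuples protected: VPS-only kinds signal NULL
  chrom$fps[[2]] <- TRUE
  expect_null(mutate_rule(chrom, 2, "canalyzing_flip"))
  expect_null(mutate_rule(chrom, 2, "canalyzed_flip"))
})

test_that("offspring always satisfy the constraints (or fall back to the parent)", {
  fx <- ga_fixture()
  set.seed(85)
  chrom <- evaluated_chromosome(fx)
  cfg <- ga_config(population_size = 10)
  for (i in 1:30) {
    off <- propose_offspring(chrom, fx$cs, fx$corr, cfg)
    expect_true(satisfies_constraints(off$network, fx$cs)$ok)
  }
})

test_that("a tiny run keeps elitism monotone and full feasibility", {
  fx <- ga_fixture()
  cfg <- ga_config(population_size = 12, n_elites = 2, max_generations = 15,
                   stop_stagnant_generations = 200, seed = 9)
  res <- evolve(fx$bm$dataset, fx$cs, cfg)
  expect_true(all(diff(res$log$best_fitness) >= 0))
  expect_true(all(res$log$feasibility_rate == 1))
  expect_true(satisfies_constraints(res$network, fx$cs)$ok)
  expect_true(res$fitness >= res$log$mean_fitness[1])
})

test_that("structure-fixed mode conserves the signed edge set bit-exactly", {
  fx <- ga_fixture()
  cfg <- ga_config(population_size = 8, n_elites = 2, max_generations = 10,
                   structure_fixed = TRUE, seed = 10)
  set.seed(10)
  start <- initialize_population(fx$cs, 10, ga_config(population_size = 2, n_elites = 0),
                                 genes = fx$bm$dataset$genes)[[1]]
  # mutate repeatedly under structure_fixed kinds: edge set must not move
  rep0 <- dynamics_accuracy(start$network, fx$bm$dataset)
  start$fitness <- rep0$dynamics_accuracy
  start$per_gene <- unname(rep0$per_gene)
  key <- function(net) {
    e <- network_edges(net)
    sort(paste(e$from, e$to, e$sign))
  }
  k0 <- key(start$network)
  cur <- start
  for (i in 1:50) {
    cur <- propose_offspring(cur, fx$cs, fx$corr, cfg)
    expect_identical(key(cur$network), k0)
    if (is.na(cur$fitness)) {
      r <- dynamics_accuracy(cur$network, fx$bm$dataset)
      cur$fitness <- r$dynamics_accuracy
      cur$per_gene <- unname(r$per_gene)
    }
  }
  # the relaxed flag preserves the unsigned edge set only
  cfg2 <- ga_config(population_size = 8, structure_fixed = TRUE,
                    structure_fixed_allow_sign_flips = TRUE, seed = 11)
  unsigned <- function(net) {
    e <- network_edges(net)
    sort(paste(e$from, e$to))
  }
  u0 <- unsigned(start$network)
  cur <- start
  for (i in 1:30) {
    cur <- propose_offspring(cur, fx$cs, fx$corr, cfg2)
    expect_identical(unsigned(cur$network), u0)
    if (is.na(cur$fitness)) {
      r <- dynamics_accuracy(cur$network, fx$bm$dataset)
      cur$fitness <- r$dynamics_accuracy
      cur$per_gene <- unname(r$per_gene)
    }
  }
})

test_that("identical seeds give identical runs regardless of worker count", {
  fx <- ga_fixture()
  run <- function(workers) {
    cfg <- ga_config(population_size = 10, max_generations = 8, seed = 123,
                     n_workers = workers)
    res <- evolve(fx$bm$dataset, fx$cs, cfg)
    f <- tempfile()
    write_network(res$network, f)
    list(log = res$log, rules = readLines(f))
  }
  a <- run(1)
  b <- run(1)
  expect_identical(a, b)
  c <- run(2)
  expect_identical(a$log, c$log)
  expect_identical(a$rules, c$rules)
})

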