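new_cs <- function(k, l, s, d, genes) {
  structure(data.frame(source = k, target = l, sign = s, directness = d,
                       stringsAsFactors = FALSE),
            genes = genes, class = c("constraint_set", "data.frame"))
}

test_that("coherency is the product of the two change directions", {
  expect_identical(coherency(c(0, 0), c(1, 1), 1, 2), 1L)    # both fall
  expect_identical(coherency(c(0, 1), c(1, 1), 1, 2), 0L)    # l unchanged
  expect_identical(coherency(c(0, 1), c(1, 0), 1, 2), -1L)   # opposite moves
  expect_error(coherency(c(0, 1), c(1, 0), 2, 2), "mutated gene")
})

test_that("gene correlation handles perfect, inverse and orthogonal columns", {
  E <- cbind(a = c(0, 0, 1, 1), b = c(0, 0, 1, 1), c = c(1, 1, 0, 0),
             d = c(0, 1, 0, 1), e = c(1, 1, 1, 1))
  expect_equal(gene_correlation(E, 1, 2), 1)
  expect_equal(gene_correlation(E, 1, 3), -1)
  expect_equal(gene_correlation(E, 1, 4), 0)
  expect_equal(gene_correlation(E, 1, 5), 0)  # zero variance -> 0 by decision
})

test_that("the (coherency, correlation) plane maps exactly onto the four classes", {
  params <- constraint_params(alpha = 0.1, beta = 0.5)
  grid_r <- c(-0.9, -0.6, -0.5, -0.3, -0.11, -0.1, -0.05, 0, 0.05, 0.1,
              0.11, 0.3, 0.5, 0.6, 0.9)
  for (delta in c(-1L, 0L, 1L)) {
    for (r in grid_r) {
      got <- classify_path_constraint(delta, r, params)
      expected <- if (delta > 0 && r >= 0.5) list(1L, "direct")
        else if (delta > 0 && r > 0.1) list(1L, "indirect")
        else if (delta < 0 && r <= -0.5) list(-1L, "direct")
        else if (delta < 0 && r < -0.1) list(-1L, "indirect")
        else NULL
      if (is.null(expected)) {
        expect_null(got)
      } else {
        expect_identical(got$sign, expected[[1]])
        expect_identical(got$directness, expected[[2]])
      }
    }
  }
  # sign mismatch between coherency and correlation yields nothing
  expect_null(classify_path_constraint(1L, -0.7, params))
  expect_null(classify_path_constraint(-1L, 0.7, params))
})

test_that("constraints derive from engineered data as per the decision table", {
  # v1 KO flips v2 the same way (positive coherency) and the columns
  # correlate perfectly -> direct positive constraint 1 -> 2
  ann <- data.frame(id = c("WT01", "KO01"), MG = c(NA, "v1"),
                    ET = c("WT", "KO"), WT = c(NA, "WT01"),
                    stringsAsFactors = FALSE)
  bool <- rbind(c(1, 1, 0), c(0, 0, 0))
  ds <- expression_dataset(paste0("v", 1:3), ann, bool = bool)
  cs <- derive_constraints(ds)
  expect_identical(nrow(cs), 1L)
  expect_identical(cs$source, 1L)
  expect_identical(cs$target, 2L)
  expect_identical(cs$sign, 1L)
  expect_identical(cs$directness, "direct")
  # at most one constraint per ordered pair
  expect_false(anyDuplicated(cs[c("source", "target")]) > 0)
})

test_that("mixed coherency signs across a gene's perturbations veto the pair", {
  ann <- data.frame(id = c("WT01", "WT02", "OE01", "OE02"),
                    MG = c(NA, NA, "v1", "v1"),
                    ET = c("WT", "WT", "OE", "OE"),
                    WT = c(NA, NA, "WT01", "WT02"),
                    stringsAsFactors = FALSE)
  # both rows overexpress v1 (0 -> 1) but v2 falls against WT01 and rises
  # against WT02: coherencies -1 and +1 -> no constraint on (1, 2)
  bool <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 1), c(1, 1, 0))
  ds <- expression_dataset(paste0("v", 1:3), ann, bool = bool)
  cs <- derive_constraints(ds)
  expect_false(any(cs$source == 1 & cs$target == 2))
})

test_that("constraint checking agrees with exhaustive path enumeration", {
  set.seed(17)
  for (rep in 1:30) {
    N <- sample(4:6, 1)
    net <- random_network(N, kmax = 3)
    edges <- network_edges(net)
    for (trial in 1:10) {
      k <- sample.int(N, 1); l <- sample(setdiff(seq_len(N), k), 1)
      s <- sample(c(-1L, 1L), 1)
      direct <- sample(c(TRUE, FALSE), 1)
      cs <- new_cs(k, l, s, if (direct) "direct" else "indirect", net$genes)
      got <- satisfies_constraints(net, cs)$ok
      want <- if (direct) {
        any(edges$from == k & edges$to == l & edges$sign == s)
      } else {
        s %in% oracle_path_signs(edges, N, k, l)
      }
      expect_identical(got, want)
    }
  }
})

test_that("an indirect constraint accepts a direct edge of the right sign", {
  net <- boolean_network(c("v1", "v2"),
                         list(ncf_rule(1, 2, 1, 1), ncf_rule(2, 1, 1, 1)))
  cs <- new_cs(1, 2, 1L, "indirect", net$genes)
  expect_true(satisfies_constraints(net, cs)$ok)
  expect_false(satisfies_constraints(net, new_cs(1, 2, -1L, "indirect",
                                                 net$genes))$ok)
})

test_that("derived constraints are signed paths of the generating network", {
  # the correlation heuristic may promote multi-hop pairs to "direct", so
  # the strict direct-edge check is not expected to hold for every pair;
  # the path-consistency semantics itself (a signed path k -> l) should
  # hold for nearly all derived constraints on noiseless data
  set.seed(29)
  tot <- 0L; path_ok <- 0L; ind_tot <- 0L; ind_ok <- 0L
  for (s in 1:15) {
    bm <- generate_benchmark(benchmark_spec(10, n_initial_states = 1000,
                                            seed = 6000 + s))
    cs <- derive_constraints(bm$dataset)
    if (!nrow(cs)) next
    as_path <- cs
    as_path$directness <- "indirect"
    chk <- satisfies_constraints(bm$network, as_path)
    tot <- tot + nrow(cs)
    path_ok <- path_ok + nrow(cs) - nrow(chk$violated)
    ind <- cs[cs$directness == "indirect", , drop = FALSE]
    if (nrow(ind)) {
      ind_tot <- ind_tot + nrow(ind)
      ind_ok <- ind_ok + nrow(ind) -
        nrow(satisfies_constraints(bm$network, ind)$violated)
    }
  }
  expect_gte(path_ok / tot, 0.95)
  expect_gte(ind_ok / max(ind_tot, 1), 0.95)
})
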