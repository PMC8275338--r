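# Independent oracles used across the suite. These deliberately re-derive
# the semantics from first principles (literal nested-if chains, full
# transition-graph enumeration, exhaustive path/partition search) and never
# call the package's own evaluation paths.

# Literal nested-if reading of a canalyzing cascade: branch m fires only if
# every earlier branch mismatched AND regulator m matches.
oracle_evaluate <- function(regs, I, O, def, state) {
  for (m in seq_along(regs)) {
    earlier_mismatch <- all(state[regs[seq_len(m - 1)]] != I[seq_len(m - 1)])
    if (earlier_mismatch && state[regs[m]] == I[m]) return(O[m])
  }
  def
}

oracle_step <- function(net, state) {
  vapply(net$rules, function(r)
    oracle_evaluate(r$regulators, r$I, r$O, r$default_out, state), integer(1))
}

state_to_int <- function(bits) sum(bits * 2^(seq_along(bits) - 1))
int_to_state <- function(x, N) as.integer(bitwAnd(x %/% 2^(0:(N - 1)), 1))

# Full 2^N transition graph; returns tau and the cycle (ordered, starting at
# v_tau) for a given initial state.
oracle_attractor <- function(net, initial) {
  N <- length(net$genes)
  nxt <- vapply(0:(2^N - 1), function(x)
    state_to_int(oracle_step(net, int_to_state(x, N))), numeric(1))
  seen <- rep(-1L, 2^N)
  path <- integer(0)
  x <- state_to_int(initial)
  t <- 0L
  while (seen[x + 1] < 0) {
    seen[x + 1] <- t
    path <- c(path, x)
    x <- nxt[x + 1]
    t <- t + 1L
  }
  tau <- seen[x + 1]
  cycle <- path[(tau + 1):length(path)]
  list(tau = tau,
       states = t(vapply(cycle, int_to_state, integer(N), N = N)))
}

# Exhaustive signed-walk enumeration by transfer-matrix DP: f_l(v, p) marks
# (node, sign-parity) pairs reachable from `from` by a walk of length l.
# Any reachable pair is reached within 2N steps (the (node, parity) state
# space has 2N elements), so the union over l = 1..2N is exact.
oracle_path_signs <- function(edges, N, from, to) {
  reach <- matrix(FALSE, N, 2)  # columns: parity +1, parity -1
  cur <- matrix(FALSE, N, 2)
  cur[from, 1] <- TRUE
  for (l in seq_len(2 * N)) {
    nxt <- matrix(FALSE, N, 2)
    for (j in seq_len(nrow(edges))) {
      u <- edges$from[j]; v <- edges$to[j]
      if (edges$sign[j] > 0) {
        nxt[v, 1] <- nxt[v, 1] | cur[u, 1]
        nxt[v, 2] <- nxt[v, 2] | cur[u, 2]
      } else {
        nxt[v, 2] <- nxt[v, 2] | cur[u, 1]
        nxt[v, 1] <- nxt[v, 1] | cur[u, 2]
      }
    }
    cur <- nxt
    reach <- reach | cur
  }
  c(1L, -1L)[c(reach[to, 1], reach[to, 2])]
}

# Exhaustive optimal 1-D 2-partition by within-cluster SSE (the global
# optimum is always a split of the sorted values).
oracle_two_means <- function(v) {
  o <- order(v)
  best <- NULL
  for (cut in 1:(length(v) - 1)) {
    lo <- v[o[1:cut]]; hi <- v[o[(cut + 1):length(v)]]
    sse <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      bits <- integer(length(v))
      bits[o[(cut + 1):length(v)]] <- 1L
      best <- list(sse = sse, bits = bits)
    }
  }
  best$bits
}

# Random NCF rule / network generators for property tests.
random_rule <- function(target, N, k = NULL) {
  k <- k %||% sample.int(min(3, N - 1), 1)
  regs <- sample(setdiff(seq_len(N), target), k)
  ncf_rule(target, regs, sample(0:1, k, TRUE), sample(0:1, k, TRUE))
}

random_network <- function(N, kmax = 3) {
  rules <- lapply(seq_len(N), function(i)
    random_rule(i, N, k = sample.int(min(kmax, N - 1), 1)))
  boolean_network(paste0("v", seq_len(N)), rules)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny hand-built 5-gene dataset following the annotated-matrix layout.
toy_dataset <- function() {
  ann <- data.frame(
    id = c("WT01", "WT02", "KO01", "KO02"),
    MG = c(NA, NA, "v1", "v3"),
    ET = c("WT", "WT", "KO", "KO"),
    WT = c(NA, NA, "WT02", "WT01"),
    stringsAsFactors = FALSE)
  bool <- rbind(c(1, 0, 1, 1, 0),
                c(1, 1, 0, 1, 0),
                c(0, 0, 0, 0, 0),
                c(0, 1, 0, 0, 1))
  expression_dataset(paste0("v", 1:5), ann, bool = bool)
}
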