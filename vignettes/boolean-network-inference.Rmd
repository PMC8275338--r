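---
title: "Inferring Boolean gene regulatory networks from steady-state perturbation data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring Boolean gene regulatory networks from steady-state perturbation data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncfga)
```

## The problem

A steady-state perturbation screen measures the stabilized expression of $N$
genes across $R$ experiments: wild-type cultures and, for each perturbed
gene, a knockout (KO) or overexpression (OE) line. Each perturbation row is
annotated with the mutated gene (MG), the experiment type (ET) and the base
wild-type experiment (WT) it derived from. From only these snapshots — no
time series — we want to recover both the *wiring* of the underlying gene
regulatory network (who regulates whom, activating or inhibiting) and its
*update logic*, so that the inferred model reproduces the observed steady
states as its attractors.

`ncfga` implements a constrained genetic algorithm for this problem. Two
ideas carry the method:

1. **Path-consistency constraints.** Comparing a perturbation row against
   its base wild type tells us, cheaply and robustly, that a signed
   regulatory path must run from the mutated gene to every gene that
   responded. These constraints are *hard*: every candidate network in the
   search must satisfy all of them at all times.
2. **Dynamics as fitness.** Candidate networks are scored by how well the
   attractors they reach — starting from the relevant wild-type state, with
   the mutated gene clamped — agree with the observed Boolean steady states.

## The Boolean network model

Each gene $v_i$ holds a state in $\{0,1\}$ and is updated synchronously by a
*nested canalyzing function* (NCF), written as an ordered cascade of tuples
plus a default:

$$ f_i = (v_{i1}, I_1, O_1)(v_{i2}, I_2, O_2)\cdots(v_{ik}, I_k, O_k)\,O_{def} $$

Evaluation walks the cascade: the first tuple whose regulator currently
equals its canalyzing value $I_m$ forces the output to its canalyzed value
$O_m$; if none fires the default applies. We enforce $O_{def} = 1 - O_k$
(the usual convention; the rule-file reader has a permissive mode for
foreign files that break it). Each tuple induces one signed edge: $I = O$
is read as activation, $I \neq O$ as inhibition. This convention makes the
single-bit mutation operators below behave as sign switches, and flipping
both bits of a tuple — which toggles the tuple between conjunction-like and
disjunction-like behaviour within the cascade — leaves the sign unchanged.

Because updates are deterministic and synchronous, every trajectory ends in
a fixed point or a limit cycle. `find_attractor()` hashes visited states and
returns the cycle with its transient length $\tau$ and period $p$. Cycle
detection is guaranteed in exact arithmetic but the cycle length is not
bounded in practice, so trajectories exceeding `max_steps` (default 2000)
updates return the final state as a flagged period-1 pseudo-attractor; such
rows are scored against that single state and reported as truncated.
Knockouts clamp the gene to 0 and overexpression to 1 for the *whole*
trajectory, initial state included.

## Scoring

**Structural.** Inferred and true networks are compared as sets of signed
directed edges over the $2N(N-1)$ possible interactions (two signs per
ordered pair): precision $TP/(TP+FP)$, recall $TP/(TP+FN)$ and structural
accuracy $(TP+TN)/(2N(N-1))$. An edge recovered with the wrong sign counts
as one false positive plus one false negative; an unsigned comparison is
available behind `signed = FALSE` for scoring tools that do not predict
signs. Precision of an empty prediction is defined as 0.

**Dynamics.** For experiment $e$ with base wild-type expression $e_b$, the
candidate network is simulated from $e_b$ under $e$'s clamp, yielding
attractor $\alpha_e$. The per-gene similarity is the fraction of the
attractor's states that agree with the observation,
$s_i = \frac1p \sum_t \mathbf 1[e_i = v_i(t)]$, the state similarity is the
gene average $s = \frac1N\sum_i s_i$, and the dynamics accuracy is the mean
of $s$ over all experiments. The per-gene averages over experiments,
$\bar s_i$, drive the mutation-gene choice below.

## Path-consistency constraints

For a perturbation row $e$ of mutated gene $k$ and its base wild type $w$,
the *coherency* with gene $l$ is $\Delta_{k,l} = (e_k - w_k)(e_l - w_l)$:
$+1$ when both genes moved the same way, $-1$ opposite, $0$ if either did
not move. The *strength* of the pair is the Pearson correlation $r(k,l)$ of
the two Boolean columns over all experiments (defined as 0 for constant
genes). A pair is classified only when coherency and correlation agree in
sign; $|r| \ge \beta$ is read as a direct interaction, $\alpha < |r| <
\beta$ as an indirect path, and $|r| \le \alpha$ as no evidence. The
defaults $\alpha = 0.1$, $\beta = 0.5$ are the standard heuristic choice
for this constraint scheme; both are exposed via `constraint_params()`.

Decisions the scheme leaves open, resolved as follows:

* When a gene has several perturbation rows, the pair is kept only if all
  its nonzero coherencies share one sign (mixed evidence vetoes the pair) —
  contradictory hard constraints would otherwise make the search
  infeasible.
* An *indirect* constraint is satisfied by any signed directed path of
  length $\ge 1$, including a single edge: weak correlation does not
  forbid directness. Path existence is decided by signed-parity
  reachability (breadth-first search over (gene, sign-product) pairs), so
  walks through cycles count, as they do dynamically.
* Boundary values: $r = \beta$ is direct, $|r| = \alpha$ is nothing.

A caveat verified by the test suite: on 10-gene benchmarks with ~12 Boolean
experiments, nearly all derived constraints are *signed paths* of the
generating network, but the directness heuristic frequently promotes
two-hop pairs to "direct" (short Boolean profiles correlate strongly along
chains). Hard direct constraints are therefore *data*-consistent rather
than gold-structure-consistent, which bounds the structural precision
attainable at this scale — see Limitations.

## The constrained genetic algorithm

A chromosome is a full rule set $f_1,\dots,f_N$. Tuples that realize a
direct constraint form the *fixed-path subgroup* (FPS) of their rule and
are protected from structural mutation; the rest are the *variable-path
subgroup* (VPS).

* **Initialization** (default population 200): each topology seeds all
  direct-constraint edges, grows to at least $2N-3$ edges by
  degree-preferential attachment, greedily adds a signed edge or two-hop
  path for any unsatisfied indirect constraint, and guarantees every gene
  at least one regulator (rewiring from the highest-in-degree gene).
  Canalyzing orders and unconstrained bits are uniform random.
* **Selection**: roulette wheel, $\Pr(x) = \mathrm{fit}(x) / \sum_y
  \mathrm{fit}(y)$, with a uniform fallback when all fitnesses are zero.
  The two best networks are carried unchanged (elitism); there is no
  crossover.
* **Mutation gene**: uniformly among genes with $\bar s_k < 1$ whose
  $\bar s_k$ has moved more than 2% over the last 100 generations
  (unconverged); falls back to any imperfect gene, then to any gene. The
  history is tracked per lineage (copied to offspring) by default;
  population-best tracking is available via `lineage_history = FALSE` —
  the choice is genuinely open and lineage tracking keeps the signal local
  to the chromosome being mutated.
* **Six mutation kinds**, chosen uniformly: canalyzing-value flip (VPS;
  switches the edge sign), canalyzed-value flip (VPS; switches the sign
  and the conjunction/disjunction role), both-bits flip (any tuple; sign
  preserved), order swap (two tuples within the same subgroup), tuple
  removal (VPS; rules keep at least one tuple) and tuple insertion (new
  regulator $v \neq v_k$ not already present with $|r(v,k)| > \alpha$, at
  the head of the VPS part). Kinds with no eligible tuple are resampled
  freely; offspring violating any constraint are discarded and the
  mutation retried, with constraint violations counting toward a retry cap
  (default 100) after which the parent is copied unchanged.
* **Stopping**: after 200 generations without strict improvement of the
  best fitness (ties do not reset the counter), at `max_generations`, or —
  since the fitness is bounded by 1 — immediately upon reaching a perfect
  score (`stop_on_perfect`, on by default, prunes a provably stagnant
  tail).
* **Parallel evaluation contract**: fitness evaluation is read-only per
  chromosome and consumes no random numbers, so `n_workers > 1`
  (fork-based) yields byte-identical runs to sequential evaluation; all
  randomness is confined to the sequential breeding phase.

The *structure-fixed* mode reuses the same machinery to fit update rules to
a fixed wiring (e.g. a structure proposed by another tool): removal and
insertion are disabled, and by default the two single-bit flips as well,
since they change edge signs; `structure_fixed_allow_sign_flips = TRUE`
relaxes this to the literal reading in which only the unsigned structure is
conserved.

## The synthetic benchmark generator

`generate_benchmark()` emulates the artificial-data protocol that the
method is evaluated on, and is first-class, tested code:

* **Topology**: undirected Barabási–Albert growth with two seed nodes and
  two attachments per new node — exactly $2N-3$ edges, matching the
  benchmark family $|A| = 2|V| - 3$ — then uniform random edge
  orientation. This particular growth scheme was chosen because it
  reproduces that printed edge count exactly. Genes left without
  regulators get one incoming edge rewired from the highest-in-degree
  gene.
* **Rules**: uniform random canalyzing order and uniform random $I$, $O$
  bits.
* **Wild types**: attractors reached from 10000 uniform random initial
  states (the protocol's count); one row per distinct attractor, most
  frequent first, capped at 10 rows (the protocol does not state a cap; 10
  keeps rare attractors from dominating the experiment table). Limit
  cycles collapse to per-gene majority votes, ties to 1.
* **Perturbations**: each gene is knocked out (optionally also
  overexpressed), simulated from the most frequent wild-type row's state
  with the gene clamped, and exported the same way, annotated with
  MG/ET/WT.
* **Real-valued export**: bit $b$ maps to $\mathcal N(b\cdot\mathrm{high} +
  (1-b)\cdot\mathrm{low},\ \sigma)$ with defaults low 2, high 8 (arbitrary
  units, separated enough for 2-means at any $\sigma < 1.5$) and
  $\sigma = 0$ — the benchmark protocol computes Boolean attractors
  directly, so noise is opt-in.

What the generator does *not* emulate: measurement noise structure of real
microarrays, dosage effects, unbinarizable intermediate expression,
asynchronous or stochastic update dynamics. Tests passing on these
benchmarks therefore demonstrate internal consistency of the method, not
performance on biological data.

## Discretization

Real-valued expression is binarized per gene by 1-D 2-means: the
higher-mean cluster becomes 1. Each column is clustered with 10 random
centroid restarts (centers drawn from distinct observed values), keeping
the lowest within-cluster sum of squares; equal-SSE ties break toward the
lower split threshold, making the result deterministic given the seed.
Zero-variance genes carry no evidence of activity and map to all-0 with a
warning; missing values are rejected.

## Problem sizes used by the tests and the acceptance script

The checks run at the benchmark family's smallest published scale, which
exercises every code path while keeping a full run on a single CPU
comfortable: 10 genes, 17 edges, a full single-gene-knockout design, GA
population 50 (the stop rule, elitism and all operators unchanged), five
replicate seeds for the recovery check. Oracle-equivalence checks use 1000
random rules ($k \le 6$) and 100 random networks ($N \le 10$) against
brute-force enumeration.

## Known limitations

* **Structural precision is bounded by the constraint heuristic.** Because
  direct constraints are derived from correlations over a dozen Boolean
  rows, some of them do not correspond to true edges; every feasible
  solution must include those edges, and the dynamics fitness cannot
  remove them. At the 10-gene scale the resulting signed structural
  accuracy typically sits *below* the all-negative baseline
  $1 - |A|/(2N(N-1))$ — an inherent property of sparse-network scoring
  (the baseline is almost unbeatable when $|A| \ll 2N(N-1)$ and precision
  is imperfect), and the reason dynamics accuracy is the fitness, not
  structure.
* **Identifiability.** Many networks share the same attractors under the
  same protocol; a perfect dynamics score does not imply structural
  recovery.
* **Synchronous updates only.** Asynchronous and probabilistic schemes are
  out of scope.
* **Truncated trajectories** are scored against their final state, which
  slightly favours long-transient candidates; the flag is surfaced in all
  reports.
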