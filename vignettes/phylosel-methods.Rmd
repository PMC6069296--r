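---
title: "Selecting core-gene subsets for well-supported phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting core-gene subsets for well-supported phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosel)
```

## The problem

A core genome — the genes shared by every genome in a group of close
species — is the natural character set for a group-level phylogeny. Yet the
tree built from the full concatenated core is frequently *not*
well-supported: a few genes evolve under weaker constraints, carry
homoplasy or transferred material, and inject a discordant signal that
erodes the bootstrap support of one or more branches. Removing those genes
restores support, but removing too many discards information and weakens
the claim that the tree represents the group. `phylosel` searches for the
**largest** subset of core genes whose tree is **best supported**.

A subset of an `n`-gene catalogue is a binary word `w` of length `n` (genes
sorted alphabetically; bit `j` = 1 keeps gene `j`). Each word is scored by

$$\mathrm{score}(w) = \frac{b(w) + p(w)}{2},$$

where `b` is the lowest bootstrap support of the tree inferred from the
concatenation of the selected genes and `p` is the percentage of core genes
kept. A tree is *well-supported* when all its internal supports exceed 95.
The search space has `2^n` points — for the typical `n > 100` this is far
beyond enumeration, hence metaheuristics.

## Evaluation backend

`evaluate_word()` turns a word into a record `(b, p, score, topology key,
tree)`:

1. concatenate the selected per-gene alignments in catalogue order;
2. pairwise mismatch proportions over comparable columns (gaps and
   ambiguity codes excluded pairwise);
3. Jukes–Cantor correction `d = -(3/4) log(1 - (4/3) p̂)`, with saturated
   pairs (`p̂ ≥ 3/4`, or no comparable column) capped at 5 substitutions per
   site so neighbor joining stays defined on degenerate inputs;
4. a neighbor-joining tree (`ape::nj`);
5. Felsenstein bootstrap: columns resampled with replacement to the
   original length; each internal branch's support is 100 times the
   fraction of replicate trees containing the same bipartition;
6. rooting on the user's outgroup. The split fixed by the rooting is not an
   inferred branch and is excluded from `b`.

Because a bootstrapped tree is expensive, records are memoized: a word is
never re-evaluated, and the run history (one record per distinct word) is
the raw material for all downstream reporting. The per-word resampling seed
is a hash of the context seed and the word's bits, so results do not depend
on the order in which a search reaches a word — this is what makes the
master–worker contract deterministic for any worker count.

This NJ backend plays the role of the external maximum-likelihood builder a
production pipeline would call; the package's adapter contract (a written
alignment in, a support-annotated newick out) lets such a builder replace
steps 2–5 without touching the search code. Topologies are binned by a
canonical key: the sorted set of rooted clades, ignoring branch lengths and
supports.

## The three metaheuristics

**Genetic algorithm** (`run_ga`). The initial candidate set is the all-ones
word, the `n` leave-one-gene-out words ("systematic mode"), and 200 random
words with 2–10 zeros; the 50 best survive. Each iteration adds 5 crossover
children (indices partitioned into `k ≤ n/2` subsets, the child copying
parent 1 on odd-numbered subsets — realized as classic k-point crossover
with contiguous blocks, `k` uniform on `2..⌊n/2⌋`), 5 mutants (`k` flips,
`k` uniform on `1..max(1, ⌈0.05 n⌉)`; the paper leaves the mutation size
open and small perturbations match its locality assumption), and 5 fresh
random words with fewer than 10% zeros; selection keeps the 50 best, so the
best score never decreases. The run stops when a word scores strictly above
95 or after 200 iterations. Duplicate children are discarded rather than
re-drawn, which preserves diversity and respects the cache.

**Hybrid Lasso refinement** (`hybrid_refine`). When the GA history is
dominated by topologies whose best trees still carry weak branches, the
history itself is evidence: for each topology with frequency above 10% and
each internal branch of its best tree with support below 95, regress that
branch's support on the gene-inclusion indicators,

$$\beta = \arg\min \sum_i \Big(Y_i - \sum_j \beta_j X_{ij}\Big)^2
  + \lambda \sum_j |\beta_j|,$$

and prune every gene with `β_j < 0` (freezing its bit at 0) before
relaunching the GA main loop. The objective has no intercept; the response
and non-constant columns are centered before fitting, which is equivalent
to an unpenalized intercept — raw 0/1 columns against an uncentered
response would force spurious positive coefficients. `λ` is chosen by
cross-validation by default (the consumed quantity is only the sign
pattern, which is stable across a wide `λ` range); a fixed value can be
supplied. Two row populations are supported (`scope`): the words of the
focal topology only, or the whole history with `Y_i = 0` when a word's tree
lacks the branch. The second is the package's default for the report and
refinement: a branch support is only attributable to genes whose inclusion
varies across rows, and a gene that changes the topology erases the branch
— information the all-history population retains (on pseudo-boolean
landscapes, whose topology labels are a function of the flagged-gene
pattern, the within-topology population is degenerate by construction).

**Binary PSO** (`run_bpso`). Particles carry a real velocity per gene and a
binary position; bit `j` switches on when a fresh uniform draw falls below
the sigmoid `1/(1 + e^{-v_j})`. Version I multiplies the summed inertia and
attraction trends by the constriction coefficient
`x = 2k / |2 - C - √(C(C-4))|` with `C = C1 + C2 = 4.1` and `k` uniform on
`[0,1]` redrawn per update; version II uses an inertia weight decreasing
linearly from 0.9 to 0.4 over the run with attraction weights drawn
uniformly from `[0.1, 0.5]` per update. Velocities are clamped to ±6, past
which the sigmoid is effectively saturated; the clamp prevents frozen bits.
Particles start with each bit set with probability 0.9 (near the whole core
genome). The swarm stops when a record has score ≥ 95 *and* keeps at least
90% of the genes ("a large set of included genes" is not quantified in the
source method; 90% is the package default and configurable), or at the
evaluation budget.

**Simulated annealing** (`run_sa_batch`). A batch of clients shares one
geometric cooling schedule: `n_m` Markov chains, temperature multiplied by
`C = (t_f/t_i)^{1/(n_m-1)}` between chains (and only between chains). The
printed form of the schedule in the source method does not map `t_i` to
`t_f`; the geometric reading does, and matches the stated "logarithmic
fading", so it is adopted. Every client starts at the all-ones word. A move
draws its size from a folded Gaussian capped at `move_distance_max`,
activates chosen inactive genes, and inactivates active ones with
probability `max(1/n_c, (n_z/n_c)·α)` where `n_z` counts zeros in the best
word so far — the `1/n_c` floor is needed because the mandated all-ones
start has `n_z = 0`, which would make 1→0 flips impossible and deadlock the
chain. Worsenings `Δ > 0` are accepted with the normalized Tsallis
probability

$$\Big(1 - \frac{(1-q)\,\Delta}{\bar\Delta\, t}\Big)^{1/(1-q)},$$

clamped to 0 when the base is non-positive; `q → 1` recovers the Metropolis
form `exp(-Δ/(\bar\Delta t))`. `Δ̄` is the running mean of `|Δ|` over all
proposals, seeded with 1 before the first move (the source normalizes by
"their mean" without defining a window). At each chain end a client
publishes its best to a shared store and adopts the global best if strictly
better; a client halts after 3 consecutive non-improving chains (a small
stagnation limit, as the method prescribes) and is not restarted, though
its published best keeps seeding others. A final greedy single-flip descent
(`greedy_descent`) polishes the batch best. The same schedule and
acceptance run on the classical two-dimensional benchmarks (three-hump
camel, Booth, Lévi N.13) through `run_sa_continuous` with a Gaussian move,
which is how the cooling parameters were validated.

Defaults follow the study conditions: `t_i = 100`, `t_f = 1e-10`,
`n_m = 13` chains, `q = 0.25`, 3 clients.

## Synthetic data

Two generators make every component testable without downloads.

**Pseudo-boolean landscapes** (`landscape_spec`) declare a set `B` of bad
genes and a penalty: `b(w) = max(0, 100 - penalty · |active ∩ B|)`, `p` and
the score as usual, and a topology label synthesized from the active-bad
pattern. No tree is built, evaluations are microseconds, and for `n ≤ 16`
the optimum is brute-forced by enumeration (`landscape_optimum`) — the
oracle against which all four search variants are checked.

**Planted alignments** (`planted_dataset`) emulate the empirical situation
the method targets. A random species tree over 6 taxa (outgroup on a long
basal branch) has one near-zero internal branch — a rapid radiation, set to
0.004 substitutions/site against 0.015–0.03 elsewhere — which is the hard
branch real groups exhibit: 17 good genes of 300 bp cannot resolve it
decisively. The 3 planted genes evolve, at 3× rate, on the
nearest-neighbor-interchange rearrangement of exactly that branch, with the
alternative resolution's central branch set to 1.5× the true one. An NNI is
the minimal topological perturbation: its discordant signal scales with the
central branch lengths only, so the planted genes contest the weak branch
without overwhelming the rest of the tree. All sequences are gap-free
Jukes–Cantor (simulation and inference deliberately share the model — the
tests probe the selection machinery, not model misspecification). Under
these conditions, including the planted genes lowers the minimum support of
the full-core tree relative to the good-genes-only tree in 9 of 10 seeds,
while the good genes alone recover the true species topology in 9 of 10 —
the tenth radiating branch being genuinely unresolvable, as intended.

What the generator does **not** emulate: rate heterogeneity across sites,
indels and alignment error, annotation noise, and model misspecification.
Passing tests therefore show that the search, scoring, binning and
attribution machinery behaves as specified on data whose ground truth is
known — not that NJ/JC is an adequate inference engine for any particular
empirical dataset (production use plugs an external ML builder into the
adapter contract).

## Numerical and design choices

* Alphabetical gene order is byte-wise (`sort(method = "radix")`), so
  catalogues are locale-independent.
* Score ties break toward larger `p`, then lexicographic word order: the
  objective prefers the largest subset at equal support, and determinism
  requires a total order.
* The GA stop comparison is strict (`> 95`), the swarm's inclusive
  (`≥ 95`), both following the source's wording; both are configurable.
* The Jukes–Cantor saturation cap is 5 substitutions/site.
* Bootstrap resampling is the standard Felsenstein bootstrap (columns drawn
  with replacement to full length); the looser "neglect random columns"
  description is read as this standard procedure for comparability.
* `glmnet` solves the Lasso; the Eq.-objective penalty maps to the glmnet
  scale as `λ_glmnet = λ/(2m)`. Single-predictor designs are padded with a
  zero column (glmnet requires two); the pad's coefficient is provably
  zero and is dropped.
* Landscape and alignment contexts share one evaluation surface, so every
  optimizer runs unchanged on either.

## Problem sizes used in the test-suite

The packaged tests run the full pipeline at deliberately small sizes: the
brute-force equivalence suite uses `n = 12` landscapes (4096 words
enumerated, budgets of 2000–2500 evaluations, 10 seeds per optimizer);
planted-data checks use the 6-taxon, 20-gene, 300-bp defaults with 100
bootstrap replicates and 10 seeds; the continuous annealing benchmark uses
the 13-chain default schedule. These sizes keep a full run of the suite in
the minutes range while leaving every algorithmic path exercised.

## Known limitations

* NJ/JC is a fast surrogate for the ML builder the method is designed
  around; supports from the two backends are not numerically comparable.
* The Lasso attribution assumes branch support responds approximately
  linearly (on the observed range) to gene inclusion; strongly epistatic
  gene interactions would require the interaction terms the model omits.
* With very short histories (a GA that stops during initialization) the
  topology bins are too thin for a meaningful regression; the refinement
  then degenerates to a plain relaunch, by design.
* A topology whose best tree is fully supported contributes no regression:
  the refinement addresses *unresolved* runs, and on a solvable dataset it
  is intentionally a no-op.
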