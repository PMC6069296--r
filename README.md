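# phylosel

Core-gene subset selection for well-supported phylogenies by distributed
metaheuristics.

## The problem

Given a group of close species, the core genome (the genes present in every
genome) is the natural basis for the group's phylogeny — but the tree built
from the *whole* core is often not well-supported, because a few genes
(homoplasy, transfer, weak constraint) inject a discordant signal. The task
is a two-objective search over the `2^n` subsets of an `n`-gene catalogue:
find the **largest** subset whose concatenated alignment yields the **best
supported** tree. Each candidate subset is a binary word `w`, scored by

```
score(w) = (b(w) + p(w)) / 2
```

where `b` is the lowest bootstrap support of the subset's tree (0–100) and
`p` the percentage of core genes retained; a tree is *well-supported* when
all its supports exceed 95.

The package implements three distributed metaheuristics over this space —

* an elitist **genetic algorithm** (all-ones + leave-one-gene-out
  "systematic mode" + random initialization; k-point crossover, k-flip
  mutation, random injection; 50-word elitist selection), hybridized with a
  **Lasso attribution** that regresses branch supports on gene-inclusion
  indicators and prunes negative-coefficient genes before a final GA phase;
* a **binary particle swarm optimizer** in two velocity variants
  (constriction coefficient with `C1 = C2 = 2.05`, and linearly decreasing
  inertia weight 0.9 → 0.4) with the sigmoid position rule;
* a **simulated annealing** batch with tiered geometric cooling, a biased
  Gaussian-distance move, normalized **Tsallis acceptance**
  `(1 − (1−q)Δ/(Δ̄t))^{1/(1−q)}`, end-of-chain synchronization between
  clients, stagnation-based halting and a final greedy descent —

plus the shared evaluation pipeline (concatenation → Jukes–Cantor distances
→ neighbor-joining tree → Felsenstein bootstrap supports → topology
binning, with per-word memoization) and a synthetic-data layer (sequence
simulation with planted discordant genes; brute-forceable pseudo-boolean
landscapes) that makes everything testable offline.

## Worked example

```r
library(phylosel)

set.seed(7)
ds  <- planted_dataset()                  # 6 taxa, 20 genes, 3 planted bad
ctx <- eval_context(alignments = ds$alignments, outgroup = ds$outgroup,
                    reps = 100, seed = 7)

w <- dataset_words(ds)
evaluate_word(ctx, w$all_ones)$b          # 96   <- whole core: weak branch
evaluate_word(ctx, w$good_only)$b         # 100  <- drop planted genes

res <- run_ga(ctx, ga_config(max_evals = 300), seed = 7)
res
#> GA result: best score 98 (b = 96 , p = 100 )
#>   stop: score | terminus: initialization | 0 iterations, 2 evaluations
```

Here the full core genome tree has a weak branch (minimum support 96 with
every gene, 100 once the three planted genes are dropped), and the GA
stops as soon as a word clears the score bar of 95 — for this seed already
during initialization. On a harder dataset the run
continues into the main loop; `topology_report(run_history(ctx))` then
tabulates, per tree topology, the occurrence count, frequency and the best
word's `b`, `p` and score, and `hybrid_refine(res)` fits the Lasso on the
history and relaunches the GA with the flagged genes removed.

The same searches run on pure fitness landscapes with known optima:

```r
spec <- landscape_spec(12, bad = c(3, 7), penalty = 20)
landscape_optimum(spec)$score             # 91.67, brute-forced over 4096 words
ctx  <- eval_context(landscape = spec, seed = 1)
run_bpso(ctx, swarm_config(n_particles = 10, max_evals = 2000), seed = 1)$best$score
#> 91.66667
```

A thin command-line front end (`exec/phylosel`) exposes `simulate`,
`evaluate`, `ga`, `pso`, `sa`, `refine`, `report` and `sa-bench`
subcommands over the same functions.

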