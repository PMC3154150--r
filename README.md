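# epiForge

Model-free evolution of epistatic case-control SNP datasets.

## The problem

Benchmarking gene–gene interaction (epistasis) detection methods requires
case-control datasets in which the disease signal lives in a *k*-way
genotype interaction with no usable lower-order effects. Simulating such
data from a penetrance model ties the benchmark to one model family.
epiForge instead **evolves the datasets themselves**: a dataset is the
individual of a mutation-only evolution strategy, scored by Multifactor
Dimensionality Reduction (MDR) accuracies and selected by Pareto
optimality, so no genetic model is ever imposed. It targets researchers who
develop or evaluate epistasis search methods (MDR-family approaches,
machine-learning SNP filters, exhaustive or heuristic interaction scans).

## The method in brief

A dataset is a balanced cohort: `n/2` cases and `n/2` controls typed at `k`
SNPs coded 0/1/2, initialized at Hardy–Weinberg proportions with MAF 0.5.
For a SNP subset *S*, the MDR accuracy labels each multi-locus genotype
cell by case/control majority and counts correct classifications:

    acc(S) = (1/n) Σ_cells max(cases_c, controls_c)  ∈ [0.5, 1]

Each dataset's objective vector holds, per minimized order *o*, the largest
`acc(S)` over all subsets of size *o* (↓), the full-order accuracy (↑), and
optionally the largest per-SNP Hardy–Weinberg chi-square (↓). Every
generation the Pareto-optimal datasets survive unchanged and parent the
next population via per-entry mutation (rate 0.001 at 3000 subjects).
Fronts with more than three objectives are capped at their 100 most central
("elbow") members; each run is summarized by the front member closest to
the per-objective optima (Euclidean distance). A streaming random-search
baseline and a two-sample Hotelling T² comparison quantify what evolution
buys over luck.

## Worked example

```r
library(epiForge)

cfg <- evolutionConfig(3, seed = 1)   # 3 SNPs: minimize 1-/2-way, maximize 3-way
cfg
#> EvolutionConfig: 3000 subjects x 3 SNPs, pop 1000, 2000 generations
#> mutation rate 0.001, front cap unlimited, seed 1
#> ObjectiveSpec: ↓acc1 ↓acc2 ↑acc3

res <- evolve(cfg)                    # ~6 s on one core
res
#> EvolutionResult: 2000 generations, final front 210 datasets
#> representative: acc1=0.5023 acc2=0.5107 acc3=0.8447

round(runHistory(res)[c(1, 501, 2001), ], 4)
#>      generation frontSize   acc1   acc2   acc3
#> 1             0        28 0.5033 0.5107 0.5523
#> 501         500       181 0.5000 0.5007 0.7480
#> 2001       2000       210 0.5000 0.5003 0.8513
```

The representative dataset carries a three-way MDR accuracy of 0.84 while
no single SNP classifies better than 0.502 and no SNP pair better than
0.511 — a pure three-way interaction. The history shows the two phases of
the search: lower-order effects are scrubbed within a few hundred
generations while the three-way signal keeps strengthening to the end.

Random search never gets close, even with two million tries:

```r
rs <- randomSearch(2e6, 3, seed = 1)
rs
#> RandomSearchResult: 2e+06 datasets, front 106 datasets
#> representative: acc1=0.5073 acc2=0.5227 acc3=0.5593
```

Export a run (MDR flat files + front information + config echo), or drive
everything from the shell via the installed `exec/epiforge` script:

```r
writeFrontInfo(res, "run01", saveFront = TRUE)
```

```sh
epiforge evolve --snps 4 --minimize-orders 1,2,3 --seed 7 --out-dir k4run
```

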