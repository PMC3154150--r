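---
title: "Evolving epistatic case-control datasets without a genetic model"
author: "epiForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving epistatic case-control datasets without a genetic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiForge)
```

## The problem

Methods that hunt for gene-gene interactions (epistasis) in case-control
SNP data are usually benchmarked on data simulated from a hand-written
penetrance model. That couples the benchmark to the model family the
simulator's author imagined: a method may look good simply because it is
tuned to the same family. epiForge takes the opposite route. It evolves the
datasets themselves, under selection pressure defined only by *scores* —
strong k-way association with disease, negligible lower-order association —
so the generating process never commits to a particular genetic model. The
result of each run is a Pareto front of balanced case-control datasets
whose disease signal is invisible to marginal, one-SNP-at-a-time analyses
yet strong when all k SNPs are examined jointly.

## Datasets as individuals

Each "individual" of the evolution strategy is an entire dataset: `n`
subjects (exactly `n/2` cases and `n/2` controls, always) typed at `k`
bi-allelic SNPs with genotypes coded 0/1/2 (1 = heterozygous). Datasets are
initialized by assigning every genotype independently with probabilities
(0.25, 0.5, 0.25) — Hardy-Weinberg proportions at minor allele frequency
0.5. Selection is free to drift the genotype frequencies afterwards; no
re-normalization is applied.

Internally a dataset is stored as a `GenotypeCounts` object: per-class
subject counts over the `3^k` genotype cells. Since case/control status
never changes and subjects carry no identity beyond their genotype vector,
subjects within a cell are exchangeable and this contingency table is a
lossless sufficient statistic for every score used (MDR accuracies, HWE
chi-square) and for mutation. It is what makes full-scale runs — population
1000, 2000 generations, 3000 subjects — take seconds to minutes on one core
rather than hours: scoring operates on a `3^k × population` count matrix in
compiled code instead of on one thousand `3000 × k` genotype matrices.
`asDataset()` expands counts back to a subject matrix (cases first, ordered
by cell index) whenever the flat-file representation is needed.

## MDR accuracy: the selection currency

Multifactor Dimensionality Reduction evaluates a SNP subset by collapsing
subjects onto the subset's multi-locus genotype cells, labelling each cell
*high-risk* if it holds more cases than controls and *low-risk* otherwise,
and scoring the labelling by the fraction of subjects classified correctly:

$$\mathrm{acc}(S) = \frac{1}{n}\sum_{\text{cells } c \in 3^{|S|}}
  \max(\mathrm{cases}_c,\ \mathrm{controls}_c).$$

For balanced data the accuracy ranges from 0.5 (every cell balanced) to 1
(every cell pure). Two numerical details matter:

* **Tied and empty cells.** A cell with equal case and control counts
  contributes the same amount under either label, so the tie convention is
  irrelevant to the value. We label ties low-risk, matching the usual
  display convention of darkening only case-majority cells.
* **No train/test split.** Attributes are whole-dataset accuracies.
  Selection is on the description of the dataset itself, not on estimated
  generalization, so cross-validation machinery is deliberately absent.

A dataset's objective vector (`evaluateObjectives()`) contains, for every
*minimized* order `o`, the maximum accuracy over all `choose(k, o)` subsets
of that order — the strongest lower-order signal anywhere in the dataset —
plus the single full-order accuracy, which is maximized. Enumeration is
exhaustive; at `k = 5` there are only 31 subsets. Accuracy is monotone
non-decreasing under subset refinement (splitting a cell can only raise a
sum of maxima), which is why minimizing low orders while maximizing the
full order is a genuinely conflicting, multi-objective problem.

## The Hardy-Weinberg objective

Association studies routinely discard SNPs whose pooled genotype counts
deviate from Hardy-Weinberg equilibrium, treating deviation as a genotyping
error signal. A strongly selected dataset can easily drift out of HWE, so
with `hwe = TRUE` an additional minimized objective is added: the per-SNP
chi-square deviation from HWE,

$$\chi^2 = \sum_{g \in \{0,1,2\}} \frac{(O_g - E_g)^2}{E_g},\qquad
  E = n\,(p^2,\ 2p(1-p),\ (1-p)^2),\ p = \frac{2 O_0 + O_1}{2n},$$

computed on pooled cases + controls and aggregated over the k SNPs by the
**maximum**. Both choices are genuinely open design decisions rather than
received practice: aggregating by the maximum follows the same "largest
value forms the attribute" pattern as the accuracy objectives and guards
the worst SNP — which is what a QC filter would act on — while pooling
matches the most common QC convention. `hweAggregate = "sum"` and
`hwePooled = FALSE` (controls only) are available for sensitivity checks. A
monomorphic SNP has no measurable deviation and scores 0.

## Selection: Pareto optimality, the elbow cap, the representative

No weighted combination of the objectives is assumed. A dataset survives a
generation exactly when no other dataset in the population dominates it —
is at least as good in every objective and strictly better in one
(`paretoFilter()`; datasets with identical vectors all survive, since they
are distinct datasets). Survivors pass unchanged into the next generation
(elitism) and act as parents: the population is refilled to size with
mutated copies, allocated round-robin over parents in stable order so each
parent receives an equal share (the first parents take the remainder). In
uncapped runs elitism makes the front's best value in each objective
monotone across generations — a property the test suite checks.

With four or more objectives the front would grow without bound, so those
runs cap survivors at 100: enough parents to matter, and an equal divisor
of the population of 1000. When the front exceeds the cap we keep the
members in the front's "elbow": each objective is min-max normalized over
the front to [0, 1] with 0 the best value, and the 100 members with the
smallest Euclidean distance to the all-zero ideal point survive. This
operationalizes "non-extreme individuals that are good in more than one
dimension" — a member that excels in a single objective but sits at the bad
end of another is far from the ideal point by construction. The exact
original tie-break is not recoverable from its published description, so
this distance rule is our definition; ties break by stable input order.

Because comparing whole fronts is awkward, each run is summarized by a
**representative**: the front member with the smallest Euclidean distance
to the vector of per-objective optima attained by that front. When all
objectives are accuracies the distance uses the raw scale (all components
live in [0.5, 1]); when the unbounded HWE chi-square is present, all
objectives are min-max normalized over the front first, else the chi-square
would dominate the metric.

## Mutation

The nominal rate is the probability that a single genotype entry mutates —
1 in 1000 for 3000-subject runs. A mutated entry is replaced by one of the
two *other* states with equal probability: a "mutation" that resamples the
current state is no mutation at all, and silently lowers the effective rate
by one third. Because the published description does not pin this down,
`resampleSame = TRUE` switches to uniform resampling over all three states
for sensitivity analyses (full-scale comparisons of the two semantics give
statistically indistinguishable endpoints).

The count-level operator is exact, not approximate. For each SNP in turn,
the number of mutating subjects is one `Binomial(total entries, rate)` draw
allocated to (cell, dataset) groups without replacement — the multivariate
hypergeometric allocation that is distributionally identical to independent
`Binomial(count, rate)` thinning of every cell, i.e. to flipping each
matrix entry independently. Each mutating subject then moves to the cell
implied by its new genotype. Processing SNPs sequentially keeps counts
non-negative and reproduces matrix-mutation semantics exactly, because a
move triggered at one SNP never changes a subject's genotype digit at
another. The test suite verifies that matrix-level and count-level mutation
produce the same distribution of objective vectors.

Default rates scale with sample size — 0.004 at 500 subjects, 0.002 at
1000, 0.001 at 3000, chosen by nearest log-size anchor
(`defaultMutationRate()`). The anchors come from the mutation-rate sweep
design reproduced by `sweepMutationRates()`: evolve at each candidate rate
for a fixed budget of 750 generations and rank rates by the mean full-order
accuracy of the resulting representatives.

## The random-search baseline

`randomSearch()` is the control experiment: draw millions of random
datasets from the initialization distribution and keep their Pareto front
in a streaming archive. Count-level sampling makes this cheap — the
per-class cell counts of a random dataset are exactly one multinomial draw
over the `3^k` HWE cell probabilities, so no genotype matrix is ever
materialized (`method = "matrix"` retains the explicit path; the two are
checked to agree in distribution). The archive update is order-independent
in its final result and equals the batch Pareto filter, which the tests
verify. Random search establishes how far "get lucky" reaches: with three
SNPs and two million draws the best jointly-constrained three-way accuracy
hovers near 0.54, whereas evolution reaches ≈ 0.85-0.89 — the gap the
Hotelling comparison quantifies.

`hotellingT2()` implements the two-sample Hotelling T-squared test (with a
one-sample variant) used to compare the objective vectors of evolved versus
random representatives; all objective components of the representative
enter the test. A singular pooled covariance raises an explicit error
rather than being silently pseudo-inverted.

## Reproducibility and randomness

A run consumes a single R random stream seeded once from `seed` in its
configuration; compiled kernels draw from the same stream, so `evolve()`,
`randomSearch()` and the CLI are bit-reproducible given the seed, across
the R/C++ boundary. The seed and every parameter are echoed into
`run_config.json` by `writeFrontInfo()`, and re-running from that echo
reproduces the output files byte for byte. Replicate runs in the sweep and
in the acceptance analyses use independent seeds drawn from a master seed.

## What the generator does and does not emulate

The evolved datasets emulate the *statistical signature* of pure k-way
epistasis in a balanced study: strong joint association, lower-order
associations at the noise floor, optionally HWE-compatible margins. They do
not emulate linkage disequilibrium between SNPs, realistic allele-frequency
spectra (initialization fixes MAF at 0.5), missing genotypes, covariates,
population structure, or genomic context — there are no positions or
alleles, only coded states. Tests passing on these datasets therefore
demonstrate sensitivity to model-free joint signal, not robustness to the
full messiness of real genotype data; users typically embed the evolved
SNPs among irrelevant noise SNPs before benchmarking a search method.

## Problem sizes used in the checks

The packaged tests exercise unit-level properties at small sizes (tens of
subjects, populations of a few dozen) and reproduce the full-scale summary
statistics with 3 replicate runs per configuration at the standard
parameters (3000 subjects, population 1000, 2000 generations, rate 0.001;
2,000,000 datasets per random-search repetition). Replicate counts are the
package's own choice: three independent full-scale runs estimate each mean
to well within the across-run spread reported for these quantities. The
evolved-versus-random Hotelling comparison in the tests uses 20 runs per
arm at reduced scale (500 subjects, population 200, 300 generations), where
the separation between the two arms is already enormous.

## Known limitations

* The elbow cap and the published representative rule are reconstructions
  of procedures the original description names but does not define; both
  are documented above and chosen to match the stated intent, not claimed
  to be the original code's behaviour.
* The HWE attribute's granularity (per SNP vs per dataset) and pooling are
  likewise undocumented in the source description; defaults are flagged in
  the class documentation.
* Whole-dataset accuracies mean the reported attribute is a description of
  the dataset, not an unbiased estimate of classifier performance on new
  subjects.
* Recombination operators are intentionally absent: without defensible
  building blocks, crossover would bias the generated model space.
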