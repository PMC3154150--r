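# Small-scale configs keep these runs fast; the full-scale behaviour is
# exercised in test-acceptance.R.
smallConfig <- function(..., nSubjects = 200, populationSize = 40,
                        generations = 25, seed = 1) {
  evolutionConfig(3, nSubjects = nSubjects, populationSize = populationSize,
                  generations = generations, seed = seed, ...)
}

test_that("zero generations returns the front of the initial population", {
  res <- evolve(smallConfig(generations = 0))
  expect_s4_class(res, "EvolutionResult")
  expect_identical(nrow(runHistory(res)), 1L)
  expect_equal(runHistory(res)$frontSize[1], length(frontMembers(res)))
  # all members satisfy dataset invariants
  for (m in frontMembers(res)) {
    expect_identical(sum(caseCounts(m)), 100L)
    expect_identical(sum(controlCounts(m)), 100L)
  }
})

test_that("history spans every generation and fronts stay within bounds", {
  res <- evolve(smallConfig(generations = 30))
  h <- runHistory(res)
  expect_identical(nrow(h), 31L)
  expect_identical(h$generation, as.numeric(0:30))
  expect_true(all(h$frontSize >= 1))
  expect_true(all(h$frontSize <= 40))
  expect_true(all(h$acc3 >= 0.5 & h$acc3 <= 1))
})

test_that("per-objective bests are monotone across generations in uncapped runs", {
  # elitism: survivors pass unchanged, so the front's best value in each
  # objective can never regress when no cap culls extremes
  set.seed(99)
  for (i in 1:10) {
    res <- evolve(smallConfig(seed = i, generations = 40))
    h <- runHistory(res)
    expect_true(all(diff(h$acc1) <= 1e-12))
    expect_true(all(diff(h$acc2) <= 1e-12))
    expect_true(all(diff(h$acc3) >= -1e-12))
  }
})

test_that("capped runs respect the cap and abort on pathological configs", {
  res <- evolve(smallConfig(frontCap = 5, generations = 20))
  expect_lte(length(frontMembers(res)), 5L)

  spec <- objectiveSpec(c(1, 2), 3, hwe = TRUE)
  cfgHwe <- evolutionConfig(3, spec = spec, nSubjects = 100,
                            populationSize = 30, generations = 10, seed = 2)
  expect_identical(cfgHwe@frontCap, 100L)  # auto cap with HWE active
  resHwe <- evolve(cfgHwe)
  expect_identical(colnames(objectiveMatrix(resHwe)),
                   c("acc1", "acc2", "acc3", "hwe"))

  expect_error(evolve(smallConfig(populationSize = 0)), "populationSize")
})

test_that("same seed and config reproduce the identical result", {
  a <- evolve(smallConfig(seed = 42, generations = 15))
  b <- evolve(smallConfig(seed = 42, generations = 15))
  expect_identical(objectiveMatrix(a), objectiveMatrix(b))
  expect_identical(runHistory(a), runHistory(b))
  expect_identical(caseCounts(representative(a)),
                   caseCounts(representative(b)))
})

test_that("mutation-free evolution cannot improve beyond initialization", {
  resA <- evolve(smallConfig(seed = 3, mutationRate = 0, generations = 20))
  resB <- evolve(smallConfig(seed = 3, generations = 0))
  # same seed: same initial population; rate 0 only replicates survivors,
  # so the set of attainable objective vectors never grows
  vecs <- function(r) unique(apply(round(objectiveMatrix(r), 10), 1,
                                   paste, collapse = "/"))
  expect_setequal(vecs(resA), vecs(resB))
})

test_that("default mutation rate scales with sample size", {
  expect_equal(defaultMutationRate(500), 0.004)
  expect_equal(defaultMutationRate(1000), 0.002)
  expect_equal(defaultMutationRate(3000), 0.001)
  expect_equal(defaultMutationRate(5000), 0.001)
})

test_that("sweep returns per-rate summaries with replicate accuracies", {
  tab <- sweepMutationRates(0.01, nSnps = 2, spec = objectiveSpec(1, 2),
                            nSubjects = 100, populationSize = 20,
                            generations = 10, replicates = 3, seed = 5)
  expect_identical(nrow(tab), 1L)
  acc <- attr(tab, "accuracies")
  expect_identical(dim(acc), c(1L, 3L))
  expect_equal(tab$meanAccuracy, mean(acc))
  expect_identical(tab$rank, 1L)

  two <- sweepMutationRates(c(0.05, 0.005), nSnps = 2,
                            spec = objectiveSpec(1, 2), nSubjects = 100,
                            populationSize = 20, generations = 10,
                            replicates = 2, seed = 6)
  expect_identical(sort(two$rank), 1:2)
})
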