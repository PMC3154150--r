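test_that("initialization yields balanced datasets with HWE genotype frequencies", {
  set.seed(101)
  d <- initDataset(3000, 3)
  expect_s4_class(d, "GenotypeDataset")
  expect_identical(sum(status(d) == 1L), 1500L)
  expect_identical(sum(status(d) == 0L), 1500L)
  expect_true(all(genotypes(d) %in% 0:2))

  d2 <- initDataset(2, 1)
  expect_identical(sort(status(d2)), c(0L, 1L))

  # heterozygote fraction over >= 10,000 entries within binomial 99% bounds
  g <- genotypes(initDataset(4000, 3))  # 12,000 entries
  phat <- mean(g == 1L)
  halfw <- qnorm(0.995) * sqrt(0.25 / length(g))
  expect_lt(abs(phat - 0.5), halfw)

  expect_error(initDataset(7, 3), "even")
  expect_error(initCounts(7, 3), "even")
})

test_that("count-level initialization matches the matrix-path distribution", {
  set.seed(42)
  tab <- initCounts(3000, 3)
  expect_identical(sum(caseCounts(tab)), 1500L)
  expect_identical(sum(controlCounts(tab)), 1500L)
  # chi-square of observed cells against the HWE cell probabilities
  p <- epiForge:::cellProbabilities(3)
  obs <- caseCounts(tab) + controlCounts(tab)
  chi <- sum((obs - 3000 * p)^2 / (3000 * p))
  expect_lt(chi, qchisq(0.999, df = 26))
})

test_that("contingency conversion is lossless for scoring and round-trips", {
  d <- GenotypeDataset(matrix(c(0L, 0L, 1L, 2L), ncol = 1),
                       c(1L, 0L, 1L, 0L))
  tab <- asCounts(d)
  expect_identical(caseCounts(tab), c(1L, 1L, 0L))
  expect_identical(controlCounts(tab), c(1L, 0L, 1L))

  # empty cell stays zero
  d2 <- GenotypeDataset(matrix(c(0L, 1L, 0L, 1L), ncol = 1),
                        c(1L, 1L, 0L, 0L))
  expect_identical(caseCounts(asCounts(d2))[3], 0L)

  set.seed(7)
  for (i in 1:100) {
    k <- sample(1:3, 1)
    d <- initDataset(40, k)
    tab <- asCounts(d)
    rt <- asCounts(asDataset(tab))
    expect_identical(caseCounts(rt), caseCounts(tab))
    expect_identical(controlCounts(rt), controlCounts(tab))
    for (o in seq_len(k))
      expect_equal(maxOrderAccuracy(tab, o), maxOrderAccuracy(d, o))
  }
})

test_that("validity catches malformed objects", {
  expect_error(GenotypeDataset(matrix(3L, 2, 1), c(1L, 0L)), "0, 1 or 2")
  expect_error(GenotypeDataset(matrix(0L, 3, 1), c(1L, 0L, 0L)), "balanced")
  expect_error(GenotypeCounts(c(2L, 0L, 0L), c(1L, 0L, 0L), 1), "balanced")
  expect_error(GenotypeCounts(c(-1L, 2L, 0L), c(1L, 0L, 0L), 1),
               "non-negative")
})

test_that("mutation preserves balance, rate 0 is identity, rate 1 changes all", {
  set.seed(11)
  d <- initDataset(100, 3)
  expect_identical(genotypes(mutate(d, 0)), genotypes(d))
  expect_true(all(genotypes(mutate(d, 1)) != genotypes(d)))
  m <- mutate(d, 0.5)
  expect_identical(status(m), status(d))
  expect_true(all(genotypes(m) %in% 0:2))

  tab <- asCounts(d)
  t0 <- mutate(tab, 0)
  expect_identical(caseCounts(t0), caseCounts(tab))
  t1 <- mutate(tab, 0.5)
  expect_identical(sum(caseCounts(t1)), 50L)
  expect_identical(sum(controlCounts(t1)), 50L)
  expect_error(mutate(tab, 1.5), "probability")
  expect_error(mutate(d, -0.1), "probability")
})

test_that("mean mutation count matches the binomial expectation", {
  set.seed(21)
  d <- initDataset(3000, 3)
  changed <- replicate(400, sum(genotypes(mutate(d, 0.001)) != genotypes(d)))
  # Binomial(9000, 0.001): mean 9, check within 3 standard errors
  se <- sqrt(9000 * 0.001 * 0.999 / 400)
  expect_lt(abs(mean(changed) - 9), 3 * se)
})

test_that("matrix- and table-level mutation induce the same score distribution", {
  set.seed(31)
  spec <- objectiveSpec(1, 2)
  d <- initDataset(50, 2)
  tab <- asCounts(d)
  nrep <- 1500
  rate <- 0.05
  accMat <- t(replicate(nrep, evaluateObjectives(mutate(d, rate), spec)))
  accTab <- t(replicate(nrep, evaluateObjectives(mutate(tab, rate), spec)))
  for (j in 1:2) {
    p <- suppressWarnings(ks.test(accMat[, j], accTab[, j]))$p.value
    expect_gt(p, 1e-4)
  }
})
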