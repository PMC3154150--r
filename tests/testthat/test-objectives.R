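test_that("HWE chi-square matches closed-form values and symmetries", {
  # exact HWE proportions
  expect_equal(hweChiSquare(table1snp(c(15, 20, 15), c(10, 30, 10)), 1,
                            pooled = TRUE), 0)
  # pooled (30,40,30): p = 0.5, expected (25,50,25) -> 1 + 2 + 1 = 4
  expect_equal(hweChiSquare(table1snp(c(15, 20, 15), c(15, 20, 15)), 1), 4)
  # homozygote label swap leaves the statistic unchanged
  expect_equal(hweChiSquare(table1snp(c(20, 25, 5), c(10, 25, 15)), 1),
               hweChiSquare(table1snp(c(5, 25, 20), c(15, 25, 10)), 1))
  # monomorphic SNP: no measurable deviation
  expect_equal(hweChiSquare(table1snp(c(50, 0, 0), c(50, 0, 0)), 1), 0)
  # controls-only option: control counts (16, 8, 1) give p = 0.8 and
  # expected counts exactly (16, 8, 1)
  expect_equal(hweChiSquare(table1snp(c(9, 9, 7), c(16, 8, 1)), 1,
                            pooled = FALSE), 0)
  expect_error(hweChiSquare(table1snp(c(1, 1, 0), c(1, 1, 0)), 5), "index")
})

test_that("objective vectors have the documented layout and orientations", {
  spec <- objectiveSpec(c(1, 2), 3)
  expect_identical(objectiveNames(spec), c("acc1", "acc2", "acc3"))
  expect_identical(orientations(spec), c("min", "min", "max"))
  expect_identical(nObjectives(spec), 3L)

  spec4 <- objectiveSpec(1:3, 4, hwe = TRUE)
  expect_identical(objectiveNames(spec4), c("acc1", "acc2", "acc3", "acc4",
                                            "hwe"))
  expect_identical(orientations(spec4), c("min", "min", "min", "max",
                                          "min"))
  expect_error(objectiveSpec(c(1, 3), 3), "strictly below")

  # flat table scores 0.5 everywhere
  flat <- GenotypeCounts(rep(2L, 27), rep(2L, 27), 3)
  v <- evaluateObjectives(flat, spec)
  expect_equal(unname(v), c(0.5, 0.5, 0.5))
})

test_that("evaluation equals brute-force recomputation from the matrix", {
  set.seed(808)
  for (i in 1:60) {
    k <- sample(2:3, 1)
    spec <- objectiveSpec(seq_len(k - 1), k, hwe = i %% 2 == 0)
    d <- initDataset(40, k)
    expect_equal(evaluateObjectives(d, spec), oracleObjectives(d, spec))
  }
})

test_that("a wider spec extends a narrower one on shared orders", {
  set.seed(909)
  tab <- randomTable(4, 30)
  narrow <- evaluateObjectives(tab, objectiveSpec(c(1, 2), 4))
  wide <- evaluateObjectives(tab, objectiveSpec(1:3, 4))
  expect_equal(wide[c("acc1", "acc2", "acc4")],
               narrow[c("acc1", "acc2", "acc4")])
})

test_that("HWE aggregation options behave as documented", {
  set.seed(111)
  tab <- randomTable(3, 40)
  chis <- vapply(1:3, function(s) hweChiSquare(tab, s), numeric(1))
  vmax <- evaluateObjectives(tab, objectiveSpec(c(1, 2), 3, hwe = TRUE))
  expect_equal(unname(vmax["hwe"]), max(chis))
  vsum <- evaluateObjectives(tab, objectiveSpec(c(1, 2), 3, hwe = TRUE,
                                                hweAggregate = "sum"))
  expect_equal(unname(vsum["hwe"]), sum(chis))
})

test_that("population-level HWE objective matches the single-table path", {
  set.seed(222)
  spec <- objectiveSpec(c(1, 2), 3, hwe = TRUE)
  tabs <- replicate(20, randomTable(3, 25), simplify = FALSE)
  ca <- vapply(tabs, caseCounts, integer(27))
  co <- vapply(tabs, controlCounts, integer(27))
  pop <- epiForge:::populationObjectives(ca, co, 3, spec)
  for (i in seq_along(tabs))
    expect_equal(unname(pop[, i]),
                 unname(evaluateObjectives(tabs[[i]], spec)))
})
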