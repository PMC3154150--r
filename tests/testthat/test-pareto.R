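test_that("dominance follows the definition on worked examples", {
  o3 <- c("min", "min", "max")
  expect_true(dominates(c(0.50, 0.51, 0.90), c(0.51, 0.52, 0.80), o3))
  expect_false(dominates(c(0.51, 0.52, 0.80), c(0.50, 0.51, 0.90), o3))
  # equality never dominates
  expect_false(dominates(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), o3))
  # mutually non-dominated pair
  o2 <- c("min", "max")
  expect_false(dominates(c(0.50, 0.70), c(0.51, 0.80), o2))
  expect_false(dominates(c(0.51, 0.80), c(0.50, 0.70), o2))
  expect_error(dominates(c(1, 2), c(1, 2, 3), o3), "length")
})

test_that("dominance is a strict partial order on random triples", {
  set.seed(1001)
  o <- c("min", "max", "min")
  for (i in 1:300) {
    a <- runif(3); b <- runif(3); cc <- runif(3)
    expect_false(dominates(a, a, o))                      # irreflexive
    if (dominates(a, b, o)) expect_false(dominates(b, a, o))  # antisymmetric
    if (dominates(a, b, o) && dominates(b, cc, o))
      expect_true(dominates(a, cc, o))                    # transitive
  }
})

test_that("paretoFilter matches worked examples and the brute-force oracle", {
  o <- c("min", "max")
  m <- rbind(c(0.51, 0.80), c(0.50, 0.70), c(0.52, 0.90), c(0.51, 0.60))
  expect_identical(paretoFilter(m, o), c(1L, 2L, 3L))
  expect_identical(paretoFilter(m[1, , drop = FALSE], o), 1L)
  expect_error(paretoFilter(m[0, , drop = FALSE], o), "at least one")

  # duplicated vectors are all retained
  dup <- rbind(c(0.5, 0.9), c(0.5, 0.9), c(0.51, 0.95))
  expect_identical(paretoFilter(dup, o), c(1L, 2L, 3L))

  set.seed(1111)
  for (i in 1:300) {
    d <- sample(3:5, 1)
    n <- sample(5:25, 1)
    orient <- sample(c("min", "max"), d, replace = TRUE)
    obj <- matrix(round(runif(n * d), 2), n, d)
    expect_identical(paretoFilter(obj, orient),
                     oracleParetoFilter(obj, orient))
  }
})

test_that("paretoFilter is idempotent and agrees with the streaming archive", {
  set.seed(1212)
  for (i in 1:50) {
    orient <- c("min", "min", "max")
    obj <- matrix(runif(60), ncol = 3)
    keep <- paretoFilter(obj, orient)
    sub <- obj[keep, , drop = FALSE]
    expect_identical(paretoFilter(sub, orient), seq_along(keep))
    stream <- sort(epiForge:::cpp_stream_front(
      epiForge:::minimizedColumns(obj, orient)) + 1L)
    expect_identical(stream, keep)
  }
})

test_that("capFront keeps the members nearest the normalized ideal point", {
  spec2 <- objectiveSpec(1, 2)

  # both-minimized example: extremes (0,1), (1,0) lose to (0.4, 0.4)
  obj <- rbind(c(0, 1), c(1, 0), c(0.4, 0.4))
  keep <- epiForge:::capFrontIndices(obj, c("min", "min"), 1)
  expect_identical(keep, 3L)

  # under the cap: unchanged
  set.seed(1313)
  f <- paretoFront(replicate(30, randomTable(2, 12), simplify = FALSE),
                   spec2)
  expect_identical(capFront(f, 100), f)

  capped <- capFront(f, 2)
  expect_lte(length(frontMembers(capped)), 2L)
  # capped front is a subset of the original and still non-dominated
  expect_true(all(apply(objectiveMatrix(capped), 1, function(r)
    any(apply(objectiveMatrix(f), 1, function(q) all(q == r))))))
  expect_identical(
    paretoFilter(objectiveMatrix(capped), orientations(spec2)),
    seq_len(length(frontMembers(capped))))
  # output size is min(|front|, cap)
  for (cap in c(1, 3, 100))
    expect_equal(length(frontMembers(capFront(f, cap))),
                 min(length(frontMembers(f)), cap))
})

test_that("representative selection minimizes distance to the ideal point", {
  spec2 <- objectiveSpec(1, 2)
  tabs <- replicate(3, randomTable(2, 10), simplify = FALSE)
  obj <- rbind(c(0.50, 0.60), c(0.52, 0.90), c(0.51, 0.80))
  f <- epiForge:::newParetoFront(tabs, obj, spec2)
  # ideal (0.50, 0.90); squared distances 0.09, 4e-4, 0.0101
  expect_identical(representative(f), 2L)

  singleton <- epiForge:::newParetoFront(tabs[1],
                                         obj[1, , drop = FALSE], spec2)
  expect_identical(representative(singleton), 1L)

  # representative is never dominated within its front (front property)
  set.seed(1414)
  for (i in 1:20) {
    f <- paretoFront(replicate(15, randomTable(2, 12), simplify = FALSE),
                     spec2)
    r <- representative(f)
    others <- setdiff(seq_len(length(frontMembers(f))), r)
    expect_false(any(vapply(others, function(j)
      dominates(objectiveMatrix(f)[j, ], objectiveMatrix(f)[r, ],
                orientations(spec2)), logical(1))))
  }
})

test_that("representative normalizes scales when an HWE objective is present", {
  spec <- objectiveSpec(1, 2, hwe = TRUE)
  tabs <- replicate(3, randomTable(2, 10), simplify = FALSE)
  # raw-scale distance would pick row 2 (tiny accuracy edge, huge chi-square);
  # normalized distance must pick row 1
  obj <- rbind(c(0.50, 0.90, 1.0), c(0.50, 0.91, 60.0), c(0.60, 0.95, 80.0))
  f <- epiForge:::newParetoFront(tabs, obj, spec)
  expect_identical(representative(f), 1L)
})

test_that("ParetoFront validity rejects dominated member sets", {
  spec2 <- objectiveSpec(1, 2)
  tabs <- replicate(2, randomTable(2, 10), simplify = FALSE)
  expect_error(
    epiForge:::newParetoFront(tabs, rbind(c(0.5, 0.9), c(0.6, 0.8)), spec2),
    "non-dominated")
})
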