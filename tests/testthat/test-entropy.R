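test_that("uniform weight distributions attain the log(q) maximum", {
  part <- edgePartitionFromClasses(data.frame(a = 1, b = 1, count = 7))
  for (w in c("m1", "m2", "harmonic", "sdd")) {
    expect_equal(entropyValue(edgeWeightEntropy(part, w)), log(7))
  }
  # single class: entropy equals log(count) whatever the positive weight is
  single <- edgePartitionFromClasses(data.frame(a = 2, b = 5, count = 11))
  expect_equal(entropyValue(edgeWeightEntropy(single, "rezg3")), log(11))
  # regular graph: every edge has the same weight for every measure
  expect_equal(entropyValue(edgeWeightEntropy(cycleGraph(6), "hm")), log(6))
})

test_that("edge-weight entropy matches the direct three-edge evaluation", {
  part <- edgePartitionFromClasses(
    data.frame(a = c(2, 2), b = c(2, 3), count = c(1, 2)))
  # weights 4, 5, 5; frozen oracle: log 14 - (4 log4 + 10 log5)/14
  expect_equal(entropyValue(edgeWeightEntropy(part, "m1")), 1.0933747,
               tolerance = 1e-6)
  res <- edgeWeightEntropy(part, "m1")
  expect_equal(res@totalWeight, 14)
  expect_equal(res@nOutcomes, 3L)
})

test_that("vertex-information entropy implements the true normalizer", {
  expect_equal(entropyValue(vertexInformationEntropy(cycleGraph(4))), log(4))
  # K1,3: reverse degrees 1,3,3,3; frozen oracle log10 - 9 log3 / 10
  expect_equal(entropyValue(vertexInformationEntropy(starGraph(3))),
               1.3138340, tolerance = 1e-6)
  # any regular graph: log p
  expect_equal(entropyValue(vertexInformationEntropy(cycleGraph(9))), log(9))
  # the normalizer is p(Delta+1) - 2q, not 2q
  res <- vertexInformationEntropy(starGraph(3))
  expect_equal(res@totalWeight, 4 * (3 + 1) - 2 * 3)
})

test_that("displayed-form diagnostic follows the class-aggregated formula", {
  single <- edgePartitionFromClasses(data.frame(a = 1, b = 1, count = 1))
  expect_equal(displayedFormEntropy(single, "m2"), 0)  # F = 1, count = 1
  part <- edgePartitionFromClasses(
    data.frame(a = c(2, 2), b = c(2, 3), count = c(1, 2)))
  # frozen oracle: log 14 - (log(1*4^4) + log(2*5^5)) / 14
  expect_equal(displayedFormEntropy(part, "m1"), 1.6186635, tolerance = 1e-6)
  # differs from the true entropy by construction
  expect_gt(abs(displayedFormEntropy(part, "m1") -
                entropyValue(edgeWeightEntropy(part, "m1"))), 0.1)
  # large classes must not overflow (hm weight 81^81 as log arithmetic)
  haptx1 <- evaluateAt(haptxPartition(), 1)
  expect_true(is.finite(displayedFormEntropy(haptx1, "hm")))
  expect_equal(displayedFormEntropy(haptx1, "m1"), 6.3063, tolerance = 5e-4)
})

test_that("base change is an exact rescaling", {
  part <- edgePartition(randomConnectedGraph(14, 4, seed = 21))
  for (w in c("m1", "abc", "rezg2")) {
    e <- entropyValue(edgeWeightEntropy(part, w))
    e2 <- entropyValue(edgeWeightEntropy(part, w, base = 2))
    e10 <- entropyValue(edgeWeightEntropy(part, w, base = 10))
    expect_equal(e2 * log(2), e, tolerance = 1e-12)
    expect_equal(e10 * log(10), e, tolerance = 1e-12)
  }
})

test_that("entropy is bounded by log(q) with equality only for uniform weights", {
  for (g in randomGraphSet(30, seedBase = 700L)) {
    part <- edgePartition(g)
    q <- numEdges(g)
    singular <- hasSingularAziClass(part)
    for (sp in allSpecs()) {
      if (sp@name == "azi" && singular) next
      # abc weights all vanish on 2-regular graphs: entropy undefined there
      e <- tryCatch({
        res <- edgeWeightEntropy(part, sp)
        entropyValue(res)
      }, revent_zero_total_weight = function(cond) NA_real_)
      if (is.na(e)) next
      expect_gte(e, 0)
      expect_lte(e, log(q) + 1e-12)
    }
  }
})

test_that("entropy is invariant to class order, splitting, and weight scale", {
  df <- data.frame(a = c(1, 1, 2), b = c(2, 3, 3), count = c(4, 2, 5))
  shuffled <- df[c(3, 1, 2), ]
  split <- data.frame(a = c(1, 1, 2, 1), b = c(2, 3, 3, 2),
                      count = c(1, 2, 5, 3))   # (1,2) class split 4 = 1 + 3
  e0 <- entropyValue(edgeWeightEntropy(edgePartitionFromClasses(df), "m2"))
  expect_equal(entropyValue(edgeWeightEntropy(edgePartitionFromClasses(shuffled), "m2")), e0)
  expect_equal(entropyValue(edgeWeightEntropy(edgePartitionFromClasses(split), "m2")), e0)

  # multiplying every weight by c > 0 leaves the distribution unchanged
  w <- c(0.4, 1.7, 3.2)
  cnt <- c(4L, 2L, 5L)
  base <- revent:::.entropyFromWeights(w, cnt, exp(1), "w", sum(cnt))
  for (c0 in c(0.01, 3, 250)) {
    scaled <- revent:::.entropyFromWeights(c0 * w, cnt, exp(1), "w", sum(cnt))
    expect_equal(entropyValue(scaled), entropyValue(base), tolerance = 1e-12)
  }
})

test_that("zero weights follow the 0 log 0 convention and bad inputs error", {
  # abc weight vanishes on the (1,1) class; entropy must stay finite
  part <- edgePartitionFromClasses(
    data.frame(a = c(1, 1), b = c(1, 2), count = c(3, 4)))
  e <- entropyValue(edgeWeightEntropy(part, "abc"))
  expect_true(is.finite(e))
  # only the 4 (1,2)-edges carry weight, all equal: entropy log 4
  expect_equal(e, log(4))
  expect_error(edgeWeightEntropy(part, "abc", base = 1),
               class = "revent_bad_record")
  all11 <- edgePartitionFromClasses(data.frame(a = 1, b = 1, count = 5))
  expect_error(edgeWeightEntropy(all11, "abc"),
               class = "revent_zero_total_weight")
})
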