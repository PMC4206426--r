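test_that("confusion counts follow the standard definitions", {
  expect_equal(unclass(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))),
               c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  expect_equal(unclass(confusion(c(1, 0), c(0, 1))),
               c(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  expect_equal(unclass(confusion(rep(1, 5), rep(1, 5))),
               c(TP = 5L, TN = 0L, FP = 0L, FN = 0L))
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length mismatch")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("metric formulas recover both published performance rows", {
  # confusion counts back-solved from the reported rates at 127+127
  train <- compute_metrics(c(TP = 120, TN = 100, FP = 27, FN = 7))
  expect_equal(round(unname(train["Sn"]), 3), 0.945)
  expect_equal(round(unname(train["Sp"]), 3), 0.787)
  expect_equal(round(unname(train["Acc"]), 3), 0.866)
  expect_equal(round(unname(train["MCC"]), 4), 0.7415)
  # and at 533+90
  test <- compute_metrics(c(TP = 478, TN = 68, FP = 22, FN = 55))
  expect_equal(round(unname(test["Sn"]), 3), 0.897)
  expect_equal(round(unname(test["Sp"]), 3), 0.756)
  expect_equal(round(unname(test["Acc"]), 3), 0.876)
  expect_equal(round(unname(test["MCC"]), 4), 0.5762)
})

test_that("perfect and degenerate classifiers hit the metric bounds", {
  perfect <- compute_metrics(c(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("Sn", "Sp", "Acc", "MCC")]),
               c(1, 1, 1, 1))
  # all-positive predictor on mixed labels: zero-denominator MCC -> 0
  allpos <- compute_metrics(c(TP = 5, TN = 0, FP = 5, FN = 0))
  expect_equal(unname(allpos["MCC"]), 0)
  # no positives evaluated: Sn is not a value
  nopos <- compute_metrics(c(TP = 0, TN = 8, FP = 2, FN = 0))
  expect_true(is.nan(nopos[["Sn"]]))
  expect_error(compute_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)),
               "no evaluated")
})

test_that("metrics agree with the phi-coefficient oracle on random counts", {
  set.seed(31)
  for (i in 1:1000) {
    cts <- sample(1:60, 4, replace = TRUE)
    names(cts) <- c("TP", "TN", "FP", "FN")
    m <- compute_metrics(cts)
    expect_equal(unname(m["MCC"]),
                 phi_oracle(cts["TP"], cts["TN"], cts["FP"], cts["FN"]),
                 tolerance = 1e-12)
    expect_equal(unname(m["Sn"]), cts[["TP"]] / (cts[["TP"]] + cts[["FN"]]),
                 tolerance = 1e-12)
    expect_equal(unname(m["Sp"]), cts[["TN"]] / (cts[["TN"]] + cts[["FP"]]),
                 tolerance = 1e-12)
    expect_equal(unname(m["Acc"]), (cts[["TP"]] + cts[["TN"]]) / sum(cts),
                 tolerance = 1e-12)
  }
})

test_that("inverting all predictions negates the MCC", {
  set.seed(37)
  for (i in 1:50) {
    n <- 40
    labels <- rbinom(n, 1, 0.5)
    preds <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2 || length(unique(preds)) < 2) next
    m1 <- compute_metrics(confusion(labels, preds))
    m2 <- compute_metrics(confusion(labels, 1 - preds))
    expect_equal(unname(m1["MCC"]), -unname(m2["MCC"]), tolerance = 1e-12)
  }
})
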