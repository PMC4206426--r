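test_that("three-state discretization thresholds at mean +/- t * sd", {
  # mean 2.5, population sd sqrt(75)/2 ~ 4.330: only 10 clears the upper cut
  expect_equal(discretize_feature(c(0, 0, 0, 10)), c(0L, 0L, 0L, 1L))
  expect_equal(discretize_feature(c(5, 5, 5, 5)), rep(0L, 4))  # sd = 0
  v <- rnorm(50)
  expect_equal(discretize_feature(v, threshold_multiplier = 1e9),
               rep(0L, 50))
  # symmetric spread crosses both cuts
  expect_equal(discretize_feature(c(-10, 0, 0, 0, 0, 10)),
               c(-1L, 0L, 0L, 0L, 0L, 1L))
  expect_error(discretize_feature(numeric(0)), "empty")
  expect_error(discretize_feature(c(1, NA)), "finite")
  expect_error(discretize_feature(1:4, threshold_multiplier = 0), "positive")
})

test_that("population (1/n) sd sets the cuts, not sample sd", {
  # 2.7 sits between mean + pop sd (2.60) and mean + sample sd (2.85):
  # the population convention flags it, the sample convention would not
  v <- c(-0.7, 2.7, 2.5, 0.8, -3.1)
  expect_equal(discretize_feature(v), c(0L, 1L, 0L, 0L, -1L))
})

test_that("discretize_table passes small discrete alphabets through", {
  tab <- cbind(cont = rnorm(30), flag = rep(c(0, 1), 15),
               tri = rep(c(2, 5, 9), 10))
  st <- discretize_table(tab)
  expect_true(all(st[, "cont"] %in% c(-1L, 0L, 1L)))
  expect_equal(st[, "flag"], rep(c(0L, 1L), 15), ignore_attr = TRUE)
  expect_equal(st[, "tri"], rep(c(0L, 1L, 2L), 10), ignore_attr = TRUE)
  # bypass disabled: everything thresholded
  st2 <- discretize_table(tab, passthrough_levels = 0L)
  expect_true(all(st2 %in% c(-1L, 0L, 1L)))
})

test_that("entropy matches closed forms and the enumeration oracle", {
  expect_equal(entropy(c(0, 0, 1, 1)), 1)
  expect_equal(entropy(rep(0, 4)), 0)
  expect_equal(entropy(c(0, 0, 0, 1)), -(3 / 4) * log2(3 / 4) -
                 (1 / 4) * log2(1 / 4))
  expect_error(entropy(integer(0)), "empty")
  set.seed(11)
  for (i in 1:50) {
    v <- sample(1:4, sample(2:40, 1), replace = TRUE)
    expect_equal(entropy(v), brute_entropy(v), tolerance = 1e-12)
  }
})

test_that("mutual information matches hand-derived values", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  # H(y) = 0.8113 bits minus H(y|x) = 0.5 bits
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 1, 1)),
               0.31127812445913283, tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "length mismatch")
})

test_that("MI is symmetric, bounded and equals entropy on itself", {
  set.seed(7)
  for (i in 1:200) {
    p <- random_state_pair(sample(5:60, 1))
    mi <- mutual_information(p$x, p$y)
    expect_gte(mi, 0)
    expect_lte(mi, min(entropy(p$x), entropy(p$y)) + 1e-12)
    expect_equal(mi, mutual_information(p$y, p$x), tolerance = 1e-15)
    expect_equal(mutual_information(p$x, p$x), entropy(p$x),
                 tolerance = 1e-12)
  }
})

test_that("plug-in MI agrees with the contingency-table oracle", {
  set.seed(13)
  for (i in 1:300) {
    p <- random_state_pair(sample(2:50, 1))
    expect_equal(mutual_information(p$x, p$y), brute_mi(p$x, p$y),
                 tolerance = 1e-12)
  }
})
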