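test_that("most relevant feature is always ranked first", {
  y <- rep(c(1, 0), 10)
  ds <- labeled_dataset(cbind(A = y, B = rep(1, 20) + 0.0,
                              C = rnorm(20, sd = 0.01)), y)
  for (scheme in c("MID", "MIQ")) {
    rk <- rank_features(ds, scheme = scheme)
    expect_equal(rk$feature_names[1], "A")
    expect_equal(rk$step_score[1], rk$relevance[1])
    expect_equal(rk$redundancy[1], 0)
  }
})

test_that("ranking is a complete permutation of the features", {
  ds <- generate_dataset(synthetic_spec(20, 3, 2, 5, seed = 9))
  for (scheme in c("MID", "MIQ")) {
    rk <- rank_features(ds, scheme = scheme)
    expect_setequal(rk$feature_names, colnames(ds$table))
    expect_equal(sort(rk$order), seq_len(ncol(ds$table)))
  }
})

test_that("an exact duplicate is demoted below a weak independent signal", {
  fix <- duplicate_penalty_table()
  rk <- rank_features(fix$dataset, scheme = "MID")
  expect_equal(rk$feature_names, c("f1", "f3", "f2"))
  # second-step scores behind the pick: f2 pays full redundancy with f1
  st <- discretize_table(fix$dataset$table)
  rel <- sapply(colnames(st), function(j) brute_mi(st[, j], fix$labels))
  score_f2 <- rel[["f2"]] - brute_mi(st[, "f2"], st[, "f1"])
  score_f3 <- rel[["f3"]] - brute_mi(st[, "f3"], st[, "f1"])
  expect_lt(score_f2, 0)
  expect_gt(score_f3, score_f2)
  expect_equal(rk$step_score[2], score_f3, tolerance = 1e-12)
})

test_that("greedy ranking matches a brute-force step scan on small tables", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(10:16, 1)
    p <- sample(3:6, 1)
    y <- sample(c(rep(1L, ceiling(n / 2)), rep(0L, floor(n / 2))))
    tab <- matrix(rnorm(n * p), n, p) + outer(y, runif(p, 0, 2))
    colnames(tab) <- paste0("f", seq_len(p))
    ds <- labeled_dataset(tab, y)
    st <- discretize_table(ds$table)
    for (scheme in c("MID", "MIQ")) {
      rk <- rank_features(ds, scheme = scheme)
      expect_greedy_optimal(rk$order, st, y, scheme)
    }
  }
})

test_that("ties break toward the lowest original column index", {
  y <- rep(c(1, 0), each = 6)
  x <- rep(c(1, 0), each = 6) + 0.0
  # three identical copies: scores tie exactly at every step
  ds <- labeled_dataset(cbind(c1 = x, c2 = x, c3 = x), y)
  rk <- rank_features(ds)
  expect_equal(rk$feature_names, c("c1", "c2", "c3"))
})

test_that("first pick is scheme-invariant and immune to constant noise", {
  ds <- generate_dataset(synthetic_spec(30, 2, 0, 4, seed = 14))
  first_mid <- rank_features(ds, "MID")$feature_names[1]
  first_miq <- rank_features(ds, "MIQ")$feature_names[1]
  expect_equal(first_mid, first_miq)
  # appending an all-constant feature never displaces the first pick
  aug <- labeled_dataset(cbind(unclass(ds$table),
                               flat = rep(2.5, nrow(ds$table))),
                         ds$labels)
  expect_equal(rank_features(aug)$feature_names[1], first_mid)
})

test_that("degenerate inputs are rejected", {
  one_class <- labeled_dataset(matrix(rnorm(8), 4, 2,
                                      dimnames = list(NULL, c("a", "b"))),
                               rep(1, 4))
  expect_error(rank_features(one_class), "both classes")
})
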