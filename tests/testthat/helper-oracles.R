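# Independent oracles and fixture builders. Deliberately written as naive
# loops / alternative closed forms so they share no code with the package.

# Plug-in MI by explicit enumeration of the joint contingency table.
brute_mi <- function(x, y) {
  n <- length(x)
  ux <- unique(x)
  uy <- unique(y)
  mi <- 0
  for (a in ux) {
    px <- sum(x == a) / n
    for (b in uy) {
      pxy <- sum(x == a & y == b) / n
      py <- sum(y == b) / n
      if (pxy > 0) mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

brute_entropy <- function(v) {
  n <- length(v)
  h <- 0
  for (a in unique(v)) {
    p <- sum(v == a) / n
    h <- h - p * log2(p)
  }
  h
}

# Exhaustive per-step scan: recompute every candidate's relevance and mean
# redundancy from scratch with brute_mi, given the already-selected set.
brute_step_scores <- function(states, labels, scheme = "MID",
                              selected = integer(0), eps = 1e-12) {
  cand <- setdiff(seq_len(ncol(states)), selected)
  scores <- numeric(length(cand))
  for (i in seq_along(cand)) {
    j <- cand[i]
    rel <- brute_mi(states[, j], labels)
    if (length(selected) == 0L) {
      scores[i] <- rel
    } else {
      red <- mean(vapply(selected,
                         function(s) brute_mi(states[, j], states[, s]),
                         numeric(1)))
      scores[i] <- if (scheme == "MID") rel - red
                   else rel / max(red, eps)
    }
  }
  names(scores) <- as.character(cand)
  scores
}

# Walk a claimed ranking and check that every step's pick attains the
# maximal brute-force score (within tol, to absorb float-summation-order
# noise between mathematically tied candidates).
expect_greedy_optimal <- function(order, states, labels, scheme = "MID",
                                  tol = 1e-9) {
  selected <- integer(0)
  for (k in seq_along(order)) {
    scores <- brute_step_scores(states, labels, scheme, selected)
    pick_score <- scores[[as.character(order[k])]]
    testthat::expect_gte(pick_score, max(scores) - tol)
    selected <- c(selected, order[k])
  }
  invisible(TRUE)
}

# MCC as the phi coefficient: Pearson correlation of the expanded binary
# label/prediction vectors. An algebraically independent route to Eq. 4.
phi_oracle <- function(tp, tn, fp, fn) {
  labels <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  preds <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  suppressWarnings(stats::cor(labels, preds))
}

# 12-sample table with a near-label feature, its exact duplicate, and a
# weak independent signal; all columns already binary so discretization
# passes them through.
duplicate_penalty_table <- function() {
  y <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  f1 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  f3 <- c(1, 1, 0, 1, 0, 1, 1, 0, 0, 0, 1, 0)
  list(dataset = labeled_dataset(cbind(f1 = f1, f2 = f1, f3 = f3), y),
       labels = y)
}

# Two well-separated Gaussian clouds: linearly separable toy data.
separable_dataset <- function(n_per_class = 20, seed = 42) {
  set.seed(seed)
  x1 <- c(rnorm(n_per_class, -5, 0.3), rnorm(n_per_class, 5, 0.3))
  x2 <- c(rnorm(n_per_class, -5, 0.3), rnorm(n_per_class, 5, 0.3))
  labeled_dataset(cbind(a = x1, b = x2),
                  rep(c(0L, 1L), each = n_per_class))
}

# Random discrete vector pairs for property sweeps.
random_state_pair <- function(n, max_levels = 4) {
  list(x = sample(seq_len(sample(max_levels, 1)), n, replace = TRUE),
       y = sample(seq_len(sample(max_levels, 1)), n, replace = TRUE))
}
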