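#' Three-state discretization of a continuous feature
#'
#' Maps a real vector onto states \{-1, 0, +1\} around its mean: +1 above
#' `mean + t * sd`, -1 below `mean - t * sd`, 0 otherwise, where `sd` is the
#' population (1/n) standard deviation. A constant vector (sd = 0) maps to
#' all zeros. This is the conventional preprocessing for mutual-information
#' feature ranking of continuous variables.
#'
#' @param values Finite numeric vector.
#' @param threshold_multiplier Positive scalar t (default 1).
#' @return Integer vector of states in \{-1, 0, 1\}.
#' @export
discretize_feature <- function(values, threshold_multiplier = 1) {
  if (length(values) == 0L) stop("empty vector", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  t <- threshold_multiplier
  if (!is.numeric(t) || length(t) != 1L || t <= 0) {
    stop("threshold_multiplier must be a positive scalar", call. = FALSE)
  }
  mu <- mean(values)
  sd_pop <- sqrt(mean((values - mu)^2))
  if (sd_pop == 0) return(integer(length(values)))
  states <- integer(length(values))
  states[values > mu + t * sd_pop] <- 1L
  states[values < mu - t * sd_pop] <- -1L
  states
}

#' Discretize every column of a feature table
#'
#' Continuous columns go through [discretize_feature()]. Columns that are
#' already discrete -- at most `passthrough_levels` distinct values, e.g. a
#' 0/1 repeat-region indicator -- bypass thresholding and are recoded as
#' consecutive integer states, preserving value order.
#'
#' @param table A `feature_table` (or numeric matrix).
#' @param threshold_multiplier Passed to [discretize_feature()].
#' @param passthrough_levels Maximum distinct-value count for a column to be
#'   treated as already discrete (default 3; 0 disables the bypass).
#' @return Integer matrix of states, same dimnames as the input.
#' @export
discretize_table <- function(table, threshold_multiplier = 1,
                             passthrough_levels = 3L) {
  mat <- unclass(as.matrix(table))
  out <- matrix(0L, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (j in seq_len(ncol(mat))) {
    v <- mat[, j]
    u <- unique(v)
    if (passthrough_levels > 0L && length(u) <= passthrough_levels) {
      out[, j] <- match(v, sort(u)) - 1L
    } else {
      out[, j] <- discretize_feature(v, threshold_multiplier)
    }
  }
  out
}

#' Plug-in Shannon entropy (bits)
#'
#' Empirical entropy of a discrete vector, base 2, with the 0 log 0 = 0
#' convention.
#'
#' @param states Non-empty vector of discrete values.
#' @return Entropy in bits.
#' @export
entropy <- function(states) {
  if (length(states) == 0L) stop("empty vector", call. = FALSE)
  p <- tabulate(match(states, unique(states))) / length(states)
  -sum(p * log2(p))
}

#' Plug-in mutual information (bits)
#'
#' MI between two equal-length discrete vectors from their empirical joint
#' distribution, base 2. The plug-in estimate is always non-negative and
#' symmetric in its arguments. This is the primitive behind both the
#' relevance (feature vs. label) and redundancy (feature vs. feature) terms
#' of the mRMR criterion.
#'
#' @param x,y Equal-length vectors of discrete values.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  n <- length(x)
  if (n == 0L) stop("empty vector", call. = FALSE)
  if (length(y) != n) stop("length mismatch", call. = FALSE)
  ix <- match(x, unique(x))
  iy <- match(y, unique(y))
  nx <- max(ix)
  ny <- max(iy)
  joint <- tabulate(ix + nx * (iy - 1L), nbins = nx * ny) / n
  px <- tabulate(ix, nbins = nx) / n
  py <- tabulate(iy, nbins = ny) / n
  outer_p <- as.vector(outer(px, py))
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
  max(mi, 0)
}
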