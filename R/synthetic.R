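#' Specification for a synthetic two-class feature table
#'
#' Describes a planted-structure dataset for exercising the ranking, IFS and
#' cross-validation stages without external data. Three feature roles:
#'
#' * informative: Normal(0, 1) in class 0, Normal(delta, 1) in class 1 --
#'   delta is the between-class mean shift in standard-deviation units;
#' * redundant: a noisy copy of an informative feature (feature j copies
#'   informative feature `j mod n_informative`, plus
#'   Normal(0, redundant_noise_sd) perturbation);
#' * noise: Normal(0, 1) in both classes.
#'
#' Feature names encode the ground-truth role (`inf_`, `red_`, `noise_`).
#'
#' @param n_per_class Samples per class.
#' @param n_informative,n_redundant,n_noise Feature counts per role;
#'   `n_redundant <= n_informative`.
#' @param delta Effect size (default 2).
#' @param redundant_noise_sd Perturbation sd for redundant copies
#'   (default 0.1).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 127L, n_informative = 3L,
                           n_redundant = 2L, n_noise = 72L, delta = 2,
                           redundant_noise_sd = 0.1, seed = 1L) {
  n_per_class <- as.integer(n_per_class)
  n_informative <- as.integer(n_informative)
  n_redundant <- as.integer(n_redundant)
  n_noise <- as.integer(n_noise)
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (min(n_informative, n_redundant, n_noise) < 0L ||
      n_informative + n_redundant + n_noise < 1L) {
    stop("feature counts must be non-negative and sum to >= 1",
         call. = FALSE)
  }
  if (n_redundant > 0L && n_informative == 0L) {
    stop("redundant features require at least one informative feature",
         call. = FALSE)
  }
  if (n_redundant > n_informative) {
    stop("n_redundant must not exceed n_informative", call. = FALSE)
  }
  structure(list(n_per_class = n_per_class, n_informative = n_informative,
                 n_redundant = n_redundant, n_noise = n_noise,
                 delta = delta, redundant_noise_sd = redundant_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled dataset
#'
#' Draws the planted-structure table described by a [synthetic_spec()].
#' Deterministic given the spec's seed. The default spec (127 per class,
#' 3 + 2 + 72 features) mimics the 254-sample, 77-feature scale of a
#' balanced editing-site training table.
#'
#' @param spec A `synthetic_spec`.
#' @return A `labeled_dataset`; class 0 samples come first.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- 2L * spec$n_per_class
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  with_seed(spec$seed, {
    cols <- list()
    inf <- NULL
    if (spec$n_informative > 0L) {
      inf <- matrix(stats::rnorm(n * spec$n_informative),
                    n, spec$n_informative)
      inf[labels == 1L, ] <- inf[labels == 1L, ] + spec$delta
      colnames(inf) <- paste0("inf_", seq_len(spec$n_informative))
      cols <- c(cols, list(inf))
    }
    if (spec$n_redundant > 0L) {
      src <- ((seq_len(spec$n_redundant) - 1L) %% spec$n_informative) + 1L
      red <- inf[, src, drop = FALSE] +
        matrix(stats::rnorm(n * spec$n_redundant,
                            sd = spec$redundant_noise_sd),
               n, spec$n_redundant)
      colnames(red) <- paste0("red_", seq_len(spec$n_redundant))
      cols <- c(cols, list(red))
    }
    if (spec$n_noise > 0L) {
      noise <- matrix(stats::rnorm(n * spec$n_noise), n, spec$n_noise)
      colnames(noise) <- paste0("noise_", seq_len(spec$n_noise))
      cols <- c(cols, list(noise))
    }
    mat <- do.call(cbind, cols)
  })
  labeled_dataset(feature_table(mat), labels)
}
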