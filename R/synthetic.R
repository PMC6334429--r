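#' Simulate a microarray-like expression dataset with known informative genes
#'
#' Generates the class-conditional Gaussian structure typical of benchmark
#' microarray studies: few samples, thousands of attributes, and a small set
#' of class-informative attributes whose class means are shifted while the
#' rest is pure noise. Ground truth is returned so recovery can be scored.
#'
#' Informative attribute `j` in class `k` is drawn from a unit-variance normal
#' centred at `effect_size * c(j, k)`, where `c(j, k)` in `{0, ..., n_classes - 1}`
#' assigns distinct centres to the classes (the assignment is rotated across
#' attributes so no single class is uniformly extreme). Noise attributes are
#' standard normal for every class. Redundant attributes are noisy copies of
#' informative ones (informative value plus `N(0, noise_sd^2)`), cycling over
#' the informative set. Class sizes are balanced within one sample and the
#' informative/redundant columns are scattered at random positions. Output is
#' fully determined by `seed`.
#'
#' @param n_samples Number of samples (rows).
#' @param n_attributes Total number of attributes (columns).
#' @param n_informative Number of class-informative attributes.
#' @param n_classes Number of classes (>= 2).
#' @param effect_size Standardised mean shift delta between adjacent class
#'   centres of an informative attribute.
#' @param n_redundant Number of noisy copies of informative attributes.
#' @param noise_sd Standard deviation of the noise added to redundant copies.
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#'
#' @return A list of class `gsp_synthetic` with elements `dataset` (an
#'   [expression_dataset]), `informative` (character, ground-truth attribute
#'   names), `redundant` (character) and the generating parameters.
#'
#' @examples
#' sim <- simulate_expression(n_samples = 20, n_attributes = 50,
#'                            n_informative = 3, seed = 1)
#' sim$informative
#' @export
simulate_expression <- function(n_samples = 60, n_attributes = 500,
                                n_informative = 5, n_classes = 2,
                                effect_size = 2.5, n_redundant = 0,
                                noise_sd = 0.3, seed = 1) {
  if (n_samples < 2 || n_attributes < 1) stop_input("need n_samples >= 2 and n_attributes >= 1")
  if (n_classes < 2) stop_input("need n_classes >= 2")
  if (n_samples < n_classes) stop_input("need at least one sample per class")
  if (n_informative < 0 || n_redundant < 0) stop_input("counts must be non-negative")
  if (n_informative + n_redundant > n_attributes) {
    stop_input("n_informative + n_redundant exceeds n_attributes")
  }
  if (n_redundant > 0 && n_informative == 0) {
    stop_input("redundant attributes require at least one informative attribute")
  }
  if (!is.finite(noise_sd) || noise_sd <= 0) stop_input("noise_sd must be > 0")

  with_seed(seed, {
    classes <- paste0("C", seq_len(n_classes))
    labels <- rep_len(classes, n_samples)        # balanced within +/- 1
    k <- match(labels, classes)                  # 1-based class index

    m <- matrix(rnorm(n_samples * n_attributes), n_samples, n_attributes)
    colnames(m) <- sprintf("g%0*d", nchar(n_attributes), seq_len(n_attributes))

    special <- sample.int(n_attributes, n_informative + n_redundant)
    inf_idx <- special[seq_len(n_informative)]
    red_idx <- special[seq_len(n_redundant) + n_informative]

    for (j in seq_len(n_informative)) {
      # rotate which class sits at which centre so classes differ per attribute
      centre <- ((k - 1L + (j - 1L)) %% n_classes) * effect_size
      m[, inf_idx[j]] <- m[, inf_idx[j]] + centre
    }
    for (j in seq_len(n_redundant)) {
      src <- inf_idx[((j - 1L) %% n_informative) + 1L]
      m[, red_idx[j]] <- m[, src] + rnorm(n_samples, sd = noise_sd)
    }

    structure(list(
      dataset = expression_dataset(m, labels),
      informative = colnames(m)[inf_idx],
      redundant = colnames(m)[red_idx],
      n_samples = n_samples, n_attributes = n_attributes,
      n_informative = n_informative, n_classes = n_classes,
      effect_size = effect_size, n_redundant = n_redundant,
      noise_sd = noise_sd, seed = seed
    ), class = "gsp_synthetic")
  })
}

#' @export
print.gsp_synthetic <- function(x, ...) {
  cat(sprintf(paste0("<gsp_synthetic> %d x %d, %d classes, %d informative ",
                     "(effect %.2g), %d redundant, seed %d\n"),
              x$n_samples, x$n_attributes, x$n_classes, x$n_informative,
              x$effect_size, x$n_redundant, x$seed))
  cat(" informative:", paste(x$informative, collapse = " "), "\n")
  invisible(x)
}
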