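# Shannon entropy (base 2) of a vector of class counts, with 0*log2(0) = 0.
entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log2(p))
}

# Package-level counter of information-gain computations: lets callers verify
# that ranks are computed once per run and served from the cached table after.
the <- new.env(parent = emptyenv())
the$ig_computations <- 0L

#' Number of information-gain computations performed so far
#'
#' A monotone per-session counter incremented once per attribute each time
#' [rank_attributes()] actually computes an Information-Gain value. The engine
#' ranks once and reuses the table, so the counter makes the rank-once cache
#' contract observable.
#' @return Integer count.
#' @export
ig_computation_count <- function() the$ig_computations

#' Supervised discretization of a continuous attribute
#'
#' Bins a continuous expression vector by recursive entropy minimisation with
#' the Fayyad-Irani MDL stopping rule: at each step the cut point minimising
#' the class-entropy of the partition is accepted only if its information gain
#' exceeds the MDL coding cost. Attributes for which no cut is accepted
#' collapse to a single bin (code 0 for every sample), which is how
#' class-irrelevant attributes end up with zero Information Gain.
#'
#' @param values Numeric vector (finite).
#' @param labels Class labels aligned to `values`.
#' @param method `"mdl"` (default) or `"equal_frequency"` (unsupervised
#'   10-bin fallback).
#' @param bins Number of bins for `method = "equal_frequency"`.
#' @return Integer bin codes, 0-based, one per sample.
#' @examples
#' discretize_attribute(c(1, 1, 1, 9, 9, 9), rep(c("A", "B"), each = 3))
#' @export
discretize_attribute <- function(values, labels,
                                 method = c("mdl", "equal_frequency"),
                                 bins = 10L) {
  method <- match.arg(method)
  if (length(values) != length(labels)) stop_input("values and labels lengths differ")
  if (any(!is.finite(values))) stop_input("values must be finite")
  labels <- as.factor(labels)
  if (method == "equal_frequency") {
    br <- unique(quantile(values, probs = seq(0, 1, length.out = bins + 1L),
                          names = FALSE, type = 7))
    if (length(br) < 3) return(rep.int(0L, length(values)))
    codes <- findInterval(values, br[-c(1L, length(br))])
    return(as.integer(codes))
  }
  cuts <- mdl_cut_points(values, as.integer(labels), nlevels(labels))
  if (length(cuts) == 0) return(rep.int(0L, length(values)))
  as.integer(findInterval(values, sort(cuts)))
}

# Recursive Fayyad-Irani MDLP cut-point search. `y` are integer class codes in
# 1..k. Candidate cuts are midpoints between consecutive distinct values whose
# adjacent intervals differ in class composition (boundary points).
mdl_cut_points <- function(values, y, k) {
  ord <- order(values)
  recurse <- function(idx) {
    v <- values[idx]
    cls <- y[idx]
    n <- length(idx)
    if (n < 2) return(numeric(0))
    tab <- tabulate(cls, k)
    ent_s <- entropy_counts(tab)
    if (ent_s == 0) return(numeric(0))

    # prefix class counts over the sorted segment
    uniq_end <- which(diff(v) > 0)          # last index of each distinct value run
    if (length(uniq_end) == 0) return(numeric(0))
    best <- NULL
    prefix <- matrix(0L, n, k)
    running <- integer(k)
    for (i in seq_len(n)) {
      running[cls[i]] <- running[cls[i]] + 1L
      prefix[i, ] <- running
    }
    best_ent <- Inf
    for (i in uniq_end) {
      left <- prefix[i, ]
      right <- tab - left
      e <- (i / n) * entropy_counts(left) + ((n - i) / n) * entropy_counts(right)
      if (e < best_ent - 1e-12) {
        best_ent <- e
        best <- i
      }
    }
    gain <- ent_s - best_ent
    left <- prefix[best, ]
    right <- tab - left
    k1 <- sum(left > 0)
    k2 <- sum(right > 0)
    k0 <- sum(tab > 0)
    delta <- log2(3^k0 - 2) -
      (k0 * ent_s - k1 * entropy_counts(left) - k2 * entropy_counts(right))
    if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))
    cut <- (v[best] + v[best + 1L]) / 2
    c(recurse(idx[seq_len(best)]), cut, recurse(idx[(best + 1L):n]))
  }
  recurse(ord)
}

#' Information gain between a discretized attribute and the class label
#'
#' Computes `H(labels) - H(labels | codes)` in bits, with base-2 entropy and
#' the convention `0 * log2(0) = 0`. This is the mutual information between
#' the binned attribute and the class, and is the filter statistic used to
#' rank attributes before selection.
#'
#' @param codes Discrete codes per sample (any vector coercible to factor).
#' @param labels Class labels aligned to `codes`.
#' @return Non-negative information gain in bits.
#' @examples
#' information_gain(c(0, 0, 1, 1), c("A", "A", "B", "B"))  # 1 bit
#' information_gain(c(0, 0, 1, 1), c("A", "B", "A", "B"))  # 0 bits
#' @export
information_gain <- function(codes, labels) {
  if (length(codes) != length(labels)) stop_input("codes and labels lengths differ")
  if (length(codes) < 2) stop_input("need at least 2 samples")
  joint <- table(codes, labels)
  n <- sum(joint)
  h_y <- entropy_counts(colSums(joint))
  h_y_given_x <- 0
  for (i in seq_len(nrow(joint))) {
    ni <- sum(joint[i, ])
    if (ni > 0) h_y_given_x <- h_y_given_x + (ni / n) * entropy_counts(joint[i, ])
  }
  max(h_y - h_y_given_x, 0)
}

#' Rank attributes by Information Gain and convert ranks to weights
#'
#' `rank_attributes()` discretizes every attribute ([discretize_attribute()]),
#' computes its Information Gain against the class label, and normalises the
#' gains into weights `w_i = r_i / sum(r)` so that the weights of a dataset
#' with any informative attribute sum to 1. Attributes with zero gain carry
#' zero weight and are flagged ineligible: they are considered irrelevant and
#' are excluded from the roulette-wheel terminal pool. Ranks should be
#' computed once per run and the returned table reused (the engine does this;
#' see [ig_computation_count()]).
#'
#' `compute_weights()` performs only the normalisation step for
#' already-computed non-negative ranks.
#'
#' @param data An [expression_dataset], or a data frame with a label column.
#' @param label_column Label column name when `data` is a data frame.
#' @param method Discretization method, see [discretize_attribute()].
#' @return A tibble of class `attribute_weights` with columns `attribute`,
#'   `info_gain` (bits), `weight` and `eligible`, in dataset attribute order.
#' @export
rank_attributes <- function(data, label_column = "class",
                            method = c("mdl", "equal_frequency")) {
  method <- match.arg(method)
  ds <- as_expression_dataset(data, label_column = label_column)
  gains <- vapply(seq_len(n_attributes(ds)), function(j) {
    codes <- discretize_attribute(ds$matrix[, j], ds$labels, method = method)
    the$ig_computations <- the$ig_computations + 1L
    information_gain(codes, ds$labels)
  }, numeric(1))
  compute_weights(gains, attribute_names(ds))
}

#' @rdname rank_attributes
#' @param ranks Non-negative per-attribute Information-Gain values.
#' @param attributes Attribute names aligned to `ranks`.
#' @export
compute_weights <- function(ranks, attributes = names(ranks)) {
  if (any(!is.finite(ranks)) || any(ranks < 0)) {
    stop_input("ranks must be finite and non-negative")
  }
  if (is.null(attributes)) attributes <- paste0("a", seq_along(ranks))
  total <- sum(ranks)
  weights <- if (total > 0) ranks / total else rep.int(0, length(ranks))
  out <- tibble(
    attribute = as.character(attributes),
    info_gain = as.numeric(ranks),
    weight = weights,
    eligible = ranks > 0
  )
  class(out) <- c("attribute_weights", class(out))
  out
}

#' Roulette-wheel (proportionate) selection of attributes
#'
#' Draws attributes with probability proportional to their weight, restricted
#' to eligible (positive-gain) attributes. This is how terminal symbols are
#' chosen during population initialisation and guided mutation: attributes
#' that carry more class information occupy more of the wheel.
#'
#' @param weights An `attribute_weights` table from [rank_attributes()].
#' @param n Number of draws.
#' @return Character vector of `n` attribute names (with replacement).
#' @export
roulette_select <- function(weights, n = 1L) {
  elig <- which(weights$eligible)
  if (length(elig) == 0) {
    stop_state("no eligible attributes (all Information-Gain ranks are zero); fall back to uniform sampling")
  }
  w <- weights$weight[elig]
  idx <- elig[sample.int(length(elig), n, replace = TRUE, prob = w)]
  weights$attribute[idx]
}

# Terminal sampler closure used by gene construction: roulette over eligible
# attributes, or uniform over all attributes when every rank is zero (the
# engine warns once when activating the fallback).
make_terminal_sampler <- function(weights, uniform_fallback = FALSE) {
  if (any(weights$eligible)) {
    function(n = 1L) roulette_select(weights, n)
  } else if (uniform_fallback) {
    attrs <- weights$attribute
    function(n = 1L) attrs[sample.int(length(attrs), n, replace = TRUE)]
  } else {
    function(n = 1L) roulette_select(weights, n)  # raises the state error
  }
}
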