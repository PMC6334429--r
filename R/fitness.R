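#' Classifier specification for fitness evaluation
#'
#' Fixes the classifier whose leave-one-out accuracy scores candidate
#' subsets. The default is a linear-kernel SVM (libsvm via e1071) with
#' cost 1 and no internal scaling, so training is deterministic given the
#' data and the accuracy is reproducible bit-for-bit. A nearest-centroid
#' classifier is available as a dependency-light alternative (useful as a
#' fast test double).
#'
#' @param kind `"linear_svm"` or `"nearest_centroid"`.
#' @param cost SVM regularisation constant C.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("linear_svm", "nearest_centroid"), cost = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(cost) || cost <= 0) stop_input("cost must be > 0")
  structure(list(kind = kind, cost = cost), class = "classifier_spec")
}

svm_fit <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", scale = FALSE, cost = cost, type = "C-classification")
}

# Leave-one-out for the linear SVM using the exact support-vector shortcut:
# removing a sample that is not a support vector of the full-data solution
# leaves the solution unchanged, so its held-out prediction equals the
# full-model prediction; only support-vector folds are refit. Identical to
# refitting all n folds (the test suite checks this against a plain loop).
loocv_svm <- function(x, y, cost, counter = NULL) {
  n <- nrow(x)
  note_fit <- function(k = 1L) {
    if (!is.null(counter)) counter$trainings <- counter$trainings + k
  }
  fit <- svm_fit(x, y, cost)
  note_fit()
  ok <- predict(fit, x) == y
  for (i in fit$index) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) {
      # degenerate fold: single-class training set predicts that class
      ok[i] <- as.character(yi[1]) == as.character(y[i])
    } else {
      f2 <- svm_fit(x[-i, , drop = FALSE], droplevels(yi), cost)
      note_fit()
      ok[i] <- as.character(predict(f2, x[i, , drop = FALSE])) == as.character(y[i])
    }
  }
  mean(ok)
}

# Nearest-centroid LOOCV, vectorised: class means are recomputed with the
# held-out sample removed (closed form from sums). Ties go to the first
# class in level order.
loocv_centroid <- function(x, y, counter = NULL) {
  n <- nrow(x)
  lev <- levels(y)
  sums <- rowsum(x, y)                # class sums, rows in level order
  cnt <- as.integer(table(y))
  ok <- logical(n)
  for (i in seq_len(n)) {
    ci <- match(y[i], lev)
    if (cnt[ci] == 1L && length(lev) == 2L) {
      ok[i] <- FALSE                  # training fold holds only the other class
      next
    }
    d2 <- vapply(seq_along(lev), function(k) {
      s <- sums[k, ]
      m <- cnt[k]
      if (k == ci) { s <- s - x[i, ]; m <- m - 1L }
      if (m == 0L) return(Inf)
      mu <- s / m
      sum((x[i, ] - mu)^2)
    }, numeric(1))
    ok[i] <- lev[which.min(d2)] == as.character(y[i])
  }
  if (!is.null(counter)) counter$trainings <- counter$trainings + n
  mean(ok)
}

#' Leave-one-out cross-validated accuracy of an attribute subset
#'
#' For each sample, the classifier is trained on the remaining `n - 1`
#' samples restricted to `subset` and predicts the held-out sample; the
#' returned accuracy is the fraction of correct predictions. A degenerate
#' fold whose training set holds a single class predicts that class. The
#' computation is deterministic: the same dataset, subset and spec always
#' give the same accuracy.
#'
#' @param data An [expression_dataset] (or data frame with a label column).
#' @param subset Character vector of attribute names (non-empty, all present
#'   in the dataset).
#' @param spec A [classifier_spec()].
#' @param label_column Label column when `data` is a data frame.
#' @return Accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(data, subset, spec = classifier_spec(),
                           label_column = "class") {
  ds <- as_expression_dataset(data, label_column = label_column)
  if (length(subset) == 0) stop_input("subset must be non-empty")
  missing <- setdiff(subset, attribute_names(ds))
  if (length(missing)) {
    stop_input(sprintf("unknown attributes: %s", paste(head(missing, 5), collapse = ", ")))
  }
  x <- ds$matrix[, subset, drop = FALSE]
  switch(spec$kind,
         linear_svm = loocv_svm(x, ds$labels, spec$cost),
         nearest_centroid = loocv_centroid(x, ds$labels))
}

#' Chromosome fitness
#'
#' The fitness of chromosome *i* combines classification accuracy with a
#' parsimony reward:
#' \deqn{f_i = 2 r \, AC(i) + r \, (t - s_i) / t}
#' where `AC(i)` is the LOOCV accuracy on the expressed subset, `s_i` the
#' subset size, `t` the total number of attributes in the dataset, and `r` a
#' scalar drawn uniformly from (0.1, 1) once per generation and shared by
#' every evaluation in it (fitness values are only compared within a
#' generation). The accuracy term spans twice the parsimony term's range, so
#' accuracy always outweighs subset size.
#'
#' @param accuracy `AC` in `[0, 1]`.
#' @param subset_size `s`, number of expressed attributes.
#' @param total_attributes `t`, attribute count of the dataset.
#' @param r Random scalar, strictly inside (0.1, 1).
#' @return The scalar fitness `f`.
#' @examples
#' fitness_value(0.9, 10, 100, 0.5)  # 1.305
#' @export
fitness_value <- function(accuracy, subset_size, total_attributes, r) {
  if (any(accuracy < 0 | accuracy > 1)) stop_input("accuracy must lie in [0, 1]")
  if (any(subset_size < 0 | subset_size > total_attributes)) {
    stop_input("subset_size must lie in [0, total_attributes]")
  }
  if (any(total_attributes < 1)) stop_input("total_attributes must be >= 1")
  if (any(r <= 0.1 | r >= 1)) stop_input("r must lie strictly inside (0.1, 1)")
  2 * r * accuracy + r * (total_attributes - subset_size) / total_attributes
}

#' Accuracy cache for fitness evaluation
#'
#' LOOCV accuracy depends only on the expressed attribute set, so it is
#' memoized across chromosomes and generations under a key made of the
#' sorted subset. Counters (`hits`, `evaluations`, `trainings`) expose the
#' memoization behaviour for auditing: total classifier trainings are
#' bounded by `n_samples + 1` times the number of distinct subsets evaluated.
#'
#' @return An environment with fields `acc` (named accuracy store), `hits`,
#'   `evaluations`, `trainings`.
#' @export
fitness_cache <- function() {
  cache <- new.env(parent = emptyenv())
  cache$acc <- new.env(parent = emptyenv())
  cache$hits <- 0L
  cache$evaluations <- 0L
  cache$trainings <- 0L
  cache
}

subset_key <- function(subset) paste(sort(subset), collapse = "\x1f")

#' Evaluate a chromosome's fitness
#'
#' Extracts the expressed attribute subset ([selected_attributes()]),
#' obtains its LOOCV accuracy (from `cache` when the same subset was scored
#' before), and assembles the fitness record. A chromosome expressing no
#' attributes (possible in classic mode with a terminal root that is
#' somehow absent) receives fitness 0 and is flagged, keeping the population
#' ordering total.
#'
#' @param chromosome A `gep_chromosome`.
#' @param data An [expression_dataset].
#' @param r Per-generation fitness scalar in (0.1, 1).
#' @param spec A [classifier_spec()].
#' @param cache A [fitness_cache()] (optional but recommended).
#' @return A list of class `fitness_record`: `accuracy`, `subset_size`,
#'   `total_attributes`, `r`, `fitness`, `subset`, `empty`.
#' @export
evaluate_chromosome <- function(chromosome, data, r, spec = classifier_spec(),
                                cache = NULL) {
  ds <- as_expression_dataset(data)
  subset <- selected_attributes(chromosome)
  t_total <- n_attributes(ds)
  if (length(subset) == 0) {
    return(structure(list(accuracy = 0, subset_size = 0L,
                          total_attributes = t_total, r = r,
                          fitness = 0, subset = character(0), empty = TRUE),
                     class = "fitness_record"))
  }
  key <- subset_key(subset)
  if (!is.null(cache) && !is.null(cache$acc[[key]])) {
    cache$hits <- cache$hits + 1L
    ac <- cache$acc[[key]]
  } else {
    x <- ds$matrix[, subset, drop = FALSE]
    counter <- cache
    ac <- switch(spec$kind,
                 linear_svm = loocv_svm(x, ds$labels, spec$cost, counter),
                 nearest_centroid = loocv_centroid(x, ds$labels, counter))
    if (!is.null(cache)) {
      cache$acc[[key]] <- ac
      cache$evaluations <- cache$evaluations + 1L
    }
  }
  structure(list(accuracy = ac, subset_size = length(subset),
                 total_attributes = t_total, r = r,
                 fitness = fitness_value(ac, length(subset), t_total, r),
                 subset = subset, empty = FALSE),
            class = "fitness_record")
}

#' @export
print.fitness_record <- function(x, ...) {
  cat(sprintf("<fitness_record> AC = %.4f, s = %d / t = %d, r = %.3f, f = %.4f\n",
              x$accuracy, x$subset_size, x$total_attributes, x$r, x$fitness))
  invisible(x)
}

# Evaluator closure handed to the genetic operators: chromosome -> record.
make_evaluator <- function(data, r, spec, cache) {
  ds <- as_expression_dataset(data)
  function(chromosome) evaluate_chromosome(chromosome, ds, r, spec, cache)
}
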