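# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written in the most literal way possible (joint-count
# enumeration, per-fold refits) and never call the code paths they check.

# tiny labelled data frame with one clearly informative attribute
tiny_frame <- function(n = 8) {
  data.frame(
    g1 = c(seq_len(n / 2), seq_len(n / 2) + 10),  # separates the classes
    g2 = rep(c(0.3, 0.1), length.out = n),        # uninformative
    g3 = rep(1, n),                               # constant
    class = rep(c("A", "B"), each = n / 2),
    stringsAsFactors = FALSE
  )
}

# brute-force information gain: enumerate the joint table by looping over
# samples, then apply the entropy definition term by term
ig_oracle <- function(codes, labels) {
  codes <- as.character(codes)
  labels <- as.character(labels)
  n <- length(codes)
  ent <- function(counts) {
    counts <- counts[counts > 0]
    p <- counts / sum(counts)
    -sum(p * log2(p))
  }
  joint <- list()
  for (i in seq_len(n)) {
    key <- paste(codes[i], labels[i], sep = "\r")
    joint[[key]] <- (joint[[key]] %||% 0) + 1
  }
  xs <- unique(codes)
  ys <- unique(labels)
  cnt <- function(x, y) joint[[paste(x, y, sep = "\r")]] %||% 0
  h_y <- ent(vapply(ys, function(y) sum(vapply(xs, cnt, 0, y = y)), 0))
  h_y_x <- 0
  for (x in xs) {
    nx <- sum(vapply(ys, function(y) cnt(x, y), 0))
    h_y_x <- h_y_x + (nx / n) * ent(vapply(ys, function(y) cnt(x, y), 0))
  }
  h_y - h_y_x
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# per-fold refit leave-one-out, the literal definition, used to check the
# package's support-vector shortcut
loocv_refit_oracle <- function(ds, subset, cost = 1) {
  x <- ds$matrix[, subset, drop = FALSE]
  y <- ds$labels
  n <- nrow(x)
  ok <- logical(n)
  for (i in seq_len(n)) {
    yi <- droplevels(y[-i])
    if (nlevels(yi) < 2) {
      ok[i] <- as.character(yi[1]) == as.character(y[i])
    } else {
      fit <- e1071::svm(x[-i, , drop = FALSE], yi, kernel = "linear",
                        scale = FALSE, cost = cost, type = "C-classification")
      ok[i] <- as.character(predict(fit, x[i, , drop = FALSE])) ==
        as.character(y[i])
    }
  }
  mean(ok)
}

# deterministic stub evaluator for operator property tests: pseudo-accuracy
# is the capped weight mass of the expressed subset, so fitness depends on
# the chromosome only through its subset, exactly like the real evaluator
stub_evaluator <- function(weights, r = 0.5, t_total = nrow(weights)) {
  w <- stats::setNames(weights$weight, weights$attribute)
  function(ch) {
    subset <- selected_attributes(ch)
    if (length(subset) == 0) {
      return(list(accuracy = 0, subset_size = 0L, fitness = 0,
                  subset = character(0), empty = TRUE))
    }
    ac <- min(1, sum(w[subset], na.rm = TRUE))
    list(accuracy = ac, subset_size = length(subset),
         fitness = fitness_value(ac, length(subset), t_total, r),
         subset = subset, empty = FALSE)
  }
}

# weight table over k synthetic attribute names with given (or random) ranks
toy_weights <- function(ranks, names = paste0("a", seq_along(ranks))) {
  compute_weights(ranks, names)
}

random_toy_chromosome <- function(weights, head_size = 4, n_genes = 2) {
  shape <- gene_shape(head_size)
  sampler <- gspr:::make_terminal_sampler(weights, uniform_fallback = TRUE)
  random_chromosome(shape, n_genes, sampler)
}
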