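test_that("fitness arithmetic follows the accuracy + parsimony form", {
  expect_equal(fitness_value(1, 100, 100, 0.5), 1)      # parsimony term vanishes
  expect_equal(fitness_value(0.9, 10, 100, 0.5), 1.35)  # 2*0.5*0.9 + 0.5*0.9
  expect_equal(fitness_value(0, 0, 10, 0.9), 0.9)       # pure parsimony ceiling
  expect_error(fitness_value(1.2, 1, 10, 0.5), class = "gspr_input_error")
  expect_error(fitness_value(0.5, 11, 10, 0.5), class = "gspr_input_error")
  expect_error(fitness_value(0.5, 1, 10, 0.05), class = "gspr_input_error")
  expect_error(fitness_value(0.5, 1, 10, 1), class = "gspr_input_error")
})

test_that("fitness is monotone: increasing in accuracy, decreasing in subset size", {
  set.seed(11)
  for (i in 1:200) {
    t_total <- sample(5:200, 1)
    s <- sample(0:t_total, 1)
    r <- runif(1, 0.11, 0.99)
    ac <- runif(1)
    f <- fitness_value(ac, s, t_total, r)
    if (ac < 0.999) {
      expect_gt(fitness_value(min(ac + 1e-3, 1), s, t_total, r), f)
    }
    if (s >= 1) expect_gt(fitness_value(ac, s - 1, t_total, r), f)
    # accuracy outweighs the whole parsimony range
    expect_gt(fitness_value(1, t_total, t_total, r),
              fitness_value(0.49, 0, t_total, r))
    expect_equal(f, 2 * r * ac + r * (t_total - s) / t_total, tolerance = 1e-12)
  }
})

test_that("LOOCV accuracy matches a per-fold refit and is deterministic", {
  sim <- simulate_expression(n_samples = 30, n_attributes = 20, n_informative = 3,
                             effect_size = 2, seed = 21)
  ds <- sim$dataset
  set.seed(2)
  for (i in 1:15) {
    subset <- sample(attribute_names(ds), sample(1:6, 1))
    ac <- loocv_accuracy(ds, subset)
    expect_equal(ac, loocv_refit_oracle(ds, subset), tolerance = 1e-12)
    expect_identical(ac, loocv_accuracy(ds, subset))  # repeat run, same value
  }
})

test_that("separable ground truth scores LOOCV 1 and permuted labels score ~0.5", {
  # effect 5 puts ~5*sqrt(3) sigma between the class centroids: every fold
  # classifies its held-out sample correctly
  sim <- simulate_expression(n_samples = 40, n_attributes = 50, n_informative = 3,
                             effect_size = 5, seed = 31)
  expect_equal(loocv_accuracy(sim$dataset, sim$informative), 1)
  expect_equal(loocv_refit_oracle(sim$dataset, sim$informative), 1)

  # labels shuffled against featureless data: chance-level accuracy. LOOCV
  # is pessimistically biased (the held-out sample's class is always the
  # training minority), so the mean sits slightly below 0.5 rather than on it.
  noise <- simulate_expression(n_samples = 40, n_attributes = 10,
                               n_informative = 0, effect_size = 0, seed = 32)
  set.seed(4)
  accs <- vapply(1:30, function(i) {
    perm <- expression_dataset(noise$dataset$matrix,
                               sample(as.character(noise$dataset$labels)))
    loocv_accuracy(perm, attribute_names(perm)[1:3])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("two-sample LOOCV enumerates its degenerate folds", {
  m <- matrix(c(0, 1, 0, 1), 2, 2, dimnames = list(NULL, c("x", "y")))
  ds <- expression_dataset(m, c("A", "B"))
  # each fold trains on a single class and predicts it; both folds miss
  expect_equal(loocv_accuracy(ds, c("x", "y")), 0)
  expect_error(loocv_accuracy(ds, character(0)), class = "gspr_input_error")
  expect_error(loocv_accuracy(ds, "nope"), class = "gspr_input_error")
})

test_that("nearest-centroid LOOCV agrees with an explicit per-fold loop", {
  sim <- simulate_expression(n_samples = 21, n_attributes = 10, n_informative = 2,
                             n_classes = 3, effect_size = 2, seed = 8)
  ds <- sim$dataset
  spec <- classifier_spec("nearest_centroid")
  oracle <- function(subset) {
    x <- ds$matrix[, subset, drop = FALSE]
    y <- ds$labels
    ok <- logical(nrow(x))
    for (i in seq_len(nrow(x))) {
      tr_x <- x[-i, , drop = FALSE]
      tr_y <- droplevels(y[-i])
      mu <- rowsum(tr_x, tr_y) / as.integer(table(tr_y))
      d <- apply(mu, 1, function(m) sum((x[i, ] - m)^2))
      ok[i] <- names(which.min(d)) == as.character(y[i])
    }
    mean(ok)
  }
  set.seed(5)
  for (i in 1:10) {
    subset <- sample(attribute_names(ds), sample(1:5, 1))
    expect_equal(loocv_accuracy(ds, subset, spec), oracle(subset))
  }
})

test_that("chromosome evaluation memoizes by expressed subset and stays exact", {
  sim <- simulate_expression(n_samples = 20, n_attributes = 10, n_informative = 2,
                             effect_size = 2.5, seed = 41)
  ds <- sim$dataset
  sh <- gene_shape(3)
  # two different genotypes expressing the same set
  a <- attribute_names(ds)
  c1 <- gspr:::new_chromosome(list(gspr:::new_gene(
    c("+", a[1], a[2], a[3], a[3], a[3], a[3]), sh)), sh)
  c2 <- gspr:::new_chromosome(list(gspr:::new_gene(
    c("+", a[2], a[1], a[5], a[5], a[5], a[5]), sh)), sh)
  cache <- fitness_cache()
  r1 <- evaluate_chromosome(c1, ds, r = 0.5, cache = cache)
  expect_equal(cache$hits, 0L)
  r2 <- evaluate_chromosome(c2, ds, r = 0.5, cache = cache)
  expect_equal(cache$hits, 1L)
  expect_equal(cache$evaluations, 1L)
  expect_identical(r1$accuracy, r2$accuracy)
  # cached value equals an uncached evaluation
  r3 <- evaluate_chromosome(c1, ds, r = 0.5, cache = NULL)
  expect_identical(r3$accuracy, r1$accuracy)
  # record fields recombine to the fitness
  expect_equal(r1$fitness,
               fitness_value(r1$accuracy, r1$subset_size, r1$total_attributes, r1$r),
               tolerance = 1e-12)
})

test_that("an empty expression receives fitness zero with a flag", {
  sim <- simulate_expression(n_samples = 10, n_attributes = 5, n_informative = 1,
                             seed = 3)
  sh <- gene_shape(2)
  empty <- structure(list(genes = list(), shape = sh, n_genes = 0),
                     class = "gep_chromosome")
  rec <- evaluate_chromosome(empty, sim$dataset, r = 0.5)
  expect_true(rec$empty)
  expect_equal(rec$fitness, 0)
  expect_equal(rec$subset_size, 0L)
})
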