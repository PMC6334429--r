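small_run_config <- function(seed, ...) {
  args <- list(pop_size = 12, max_generations = 12, head_size = 4, seed = seed,
               classifier = classifier_spec("nearest_centroid"))
  do.call(gsp_config, utils::modifyList(args, list(...)))
}

test_that("a selection run recovers a separating subset on easy data", {
  sim <- simulate_expression(n_samples = 30, n_attributes = 60, n_informative = 3,
                             effect_size = 3, seed = 101)
  fit <- gsp(sim$dataset, config = small_run_config(101))
  expect_s3_class(fit, "gsp_result")
  expect_equal(fit$best_accuracy,
               loocv_accuracy(sim$dataset, fit$best_subset,
                              classifier_spec("nearest_centroid")))
  expect_gte(fit$best_accuracy, 0.9)
  expect_true(all(fit$best_subset %in% attribute_names(sim$dataset)))
})

test_that("identical seed, config and data reproduce the run bit for bit", {
  sim <- simulate_expression(n_samples = 24, n_attributes = 40, n_informative = 3,
                             effect_size = 2.5, seed = 55)
  a <- gsp(sim$dataset, config = small_run_config(55))
  b <- gsp(sim$dataset, config = small_run_config(55))
  expect_identical(a$history, b$history)
  expect_identical(a$best_subset, b$best_subset)
  expect_identical(a$best_accuracy, b$best_accuracy)
})

test_that("the hall of fame never worsens across generations", {
  sim <- simulate_expression(n_samples = 24, n_attributes = 40, n_informative = 3,
                             effect_size = 2, seed = 77)
  fit <- gsp(sim$dataset, config = small_run_config(77))
  h <- tidy(fit)
  expect_true(all(diff(h$hof_accuracy) >= 0))
  same_acc <- diff(h$hof_accuracy) == 0
  expect_true(all(diff(h$hof_size)[same_acc] <= 0))
})

test_that("classifier trainings respect the memoization bound", {
  sim <- simulate_expression(n_samples = 20, n_attributes = 30, n_informative = 2,
                             effect_size = 2.5, seed = 88)
  fit <- gsp(sim$dataset, config = small_run_config(88))
  expect_lte(fit$counters$classifier_trainings,
             n_samples(sim$dataset) * fit$counters$distinct_subsets)
})

test_that("generation cap zero reports the best of the initial population", {
  sim <- simulate_expression(n_samples = 20, n_attributes = 30, n_informative = 2,
                             effect_size = 2.5, seed = 91)
  fit <- gsp(sim$dataset, config = small_run_config(91, max_generations = 0))
  expect_equal(fit$generations_run, 0)
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$best_generation, 0)
})

test_that("stalling halts the run before the generation cap", {
  sim <- simulate_expression(n_samples = 20, n_attributes = 30, n_informative = 2,
                             effect_size = 3, seed = 92)
  fit <- gsp(sim$dataset,
             config = small_run_config(92, max_generations = 500,
                                       stall_generations = 5))
  expect_lt(fit$generations_run, 500)
  tail_rows <- utils::tail(tidy(fit), 5)
  expect_true(all(tail_rows$hof_accuracy == fit$best_accuracy))

  # the stop rule itself: cap wins, stall triggers at the threshold
  cfg <- gsp_config(max_generations = 10, stall_generations = 5)
  expect_true(stop_condition(10, 0, cfg))
  expect_true(stop_condition(3, 5, cfg))
  expect_false(stop_condition(3, 4, cfg))
})

test_that("degenerate datasets and configs are rejected", {
  sim <- simulate_expression(n_samples = 10, n_attributes = 10, n_informative = 1,
                             seed = 1)
  two <- expression_dataset(sim$dataset$matrix[1:2, ],
                            as.character(sim$dataset$labels[1:2]))
  expect_error(gsp(two), class = "gspr_input_error")
  expect_error(gsp_config(pop_size = 1), class = "gspr_input_error")
  expect_error(gsp_config(elitism = 5, pop_size = 4), class = "gspr_input_error")
})

test_that("all-zero Information Gain falls back to uniform sampling with a warning", {
  # constant attributes always discretize to one bin, so every rank is zero
  m <- matrix(rep(c(1, 2, 3, 4, 5, 6, 7, 8), each = 20), 20, 8,
              dimnames = list(NULL, paste0("g", 1:8)))
  labels <- rep(c("A", "B"), 10)
  ds <- expression_dataset(m, labels)
  w <- rank_attributes(ds)
  expect_false(any(w$eligible))
  expect_warning(
    fit <- gsp(ds, config = gsp_config(pop_size = 6, max_generations = 2,
                                       head_size = 3, seed = 3,
                                       classifier = classifier_spec("nearest_centroid"))),
    regexp = "uniform"
  )
  expect_gt(length(fit$best_subset), 0)
})

test_that("tidiers and plots summarise a run", {
  sim <- simulate_expression(n_samples = 20, n_attributes = 30, n_informative = 2,
                             effect_size = 3, seed = 61)
  fit <- gsp(sim$dataset, config = small_run_config(61))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$best_accuracy, fit$best_accuracy)
  h <- tidy(fit)
  expect_true(all(c("generation", "r", "hof_accuracy", "hof_size") %in% names(h)))
  expect_true(all(h$r > 0.1 & h$r < 1))
  sel <- selected_genes(fit)
  expect_setequal(sel$attribute, fit$best_subset)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  pw <- plot_attribute_weights(fit$weights)
  expect_s3_class(pw, "ggplot")
})
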