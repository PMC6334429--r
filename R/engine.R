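#' Configuration for a selection run
#'
#' Defaults follow the published parameterisation of the method: population
#' of 200 chromosomes, up to 2000 generations, 2 genes per chromosome with
#' head size 15 (the setting found best in the original evaluation),
#' mutation 0.044 and recombination 0.3. A stall rule (no improvement of the
#' accuracy-then-size best for `stall_generations`) ends runs that have
#' converged long before the generation cap.
#'
#' @param pop_size Chromosomes per generation.
#' @param max_generations Generation cap (0 = score the initial population
#'   only).
#' @param genes_per_chromosome Genes `N` per chromosome.
#' @param head_size Head size `h` of every gene.
#' @param rates [operator_rates()].
#' @param classifier [classifier_spec()].
#' @param fset [function_set()].
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param stall_generations Halt after this many generations without
#'   improvement of the hall-of-fame (accuracy, then smaller subset).
#' @param elitism Elites copied unchanged each generation.
#' @param classic Run with unguided classic-GEP operators (ablation).
#' @param discretization Discretization used for the Information-Gain
#'   ranking, see [discretize_attribute()].
#' @return A `gsp_config` list.
#' @export
gsp_config <- function(pop_size = 200L, max_generations = 2000L,
                       genes_per_chromosome = 2L, head_size = 15L,
                       rates = operator_rates(),
                       classifier = classifier_spec(),
                       fset = function_set(),
                       seed = 1L, stall_generations = 50L, elitism = 1L,
                       classic = FALSE,
                       discretization = c("mdl", "equal_frequency")) {
  if (pop_size < 2) stop_input("pop_size must be >= 2")
  if (max_generations < 0) stop_input("max_generations must be >= 0")
  if (genes_per_chromosome < 1) stop_input("genes_per_chromosome must be >= 1")
  if (head_size < 1) stop_input("head_size must be >= 1")
  if (stall_generations < 1) stop_input("stall_generations must be >= 1")
  if (elitism < 0 || elitism >= pop_size) stop_input("need 0 <= elitism < pop_size")
  structure(list(
    pop_size = as.integer(pop_size),
    max_generations = as.integer(max_generations),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    head_size = as.integer(head_size),
    rates = rates,
    classifier = classifier,
    fset = fset,
    seed = as.integer(seed),
    stall_generations = as.integer(stall_generations),
    elitism = as.integer(elitism),
    classic = isTRUE(classic),
    discretization = match.arg(discretization)
  ), class = "gsp_config")
}

config_as_list <- function(config) {
  list(pop_size = config$pop_size,
       max_generations = config$max_generations,
       genes_per_chromosome = config$genes_per_chromosome,
       head_size = config$head_size,
       mutation_rate = config$rates$mutation_rate,
       recombination_rate = config$rates$recombination_rate,
       mutation_retries = config$rates$mutation_retries,
       recombination_retries = config$rates$recombination_retries,
       classifier = config$classifier$kind,
       svm_cost = config$classifier$cost,
       seed = config$seed,
       stall_generations = config$stall_generations,
       elitism = config$elitism,
       classic = config$classic,
       discretization = config$discretization)
}

# hall-of-fame order: higher accuracy first, then smaller subset. This order
# is r-free, so it is comparable across generations (raw fitness is not).
hof_better <- function(accuracy, size, hof) {
  is.null(hof) || accuracy > hof$accuracy ||
    (accuracy == hof$accuracy && size < hof$size)
}

#' Stop rule of the generational loop
#'
#' Halts when the generation cap is reached, or when the hall-of-fame
#' (accuracy, then smaller subset) has not improved for `stall_generations`
#' generations. The cap always wins. Because the hall-of-fame order already
#' ranks equal-accuracy subsets by size, a run that has reached accuracy 1
#' keeps going for as long as the subset keeps shrinking.
#'
#' @param generations_run Breeding iterations completed.
#' @param stall Generations since the last hall-of-fame improvement.
#' @param config A [gsp_config()].
#' @return `TRUE` to halt.
#' @export
stop_condition <- function(generations_run, stall, config) {
  generations_run >= config$max_generations ||
    stall >= config$stall_generations
}

#' Run gene selection
#'
#' The full selection loop: rank all attributes once by Information Gain and
#' cache the table, convert ranks to roulette weights, initialise the
#' population with weight-guided terminal draws, then per generation draw
#' the fitness scalar `r` from (0.1, 1), evaluate every chromosome (LOOCV
#' accuracy memoized by expressed subset), update the hall of fame by
#' (accuracy, then smaller subset), and breed the next generation with
#' elitism, fitness-proportionate parent selection and the guided mutation
#' and recombination operators. The run halts per [stop_condition()] and is
#' bit-reproducible from `config$seed`.
#'
#' @param data An [expression_dataset], or a data frame / tibble holding
#'   numeric attribute columns and a label column (pipe-friendly).
#' @param label_column Label column name when `data` is a data frame.
#' @param config A [gsp_config()].
#' @param verbose Print one line per generation to stderr.
#'
#' @return A `gsp_result` with `best_subset`, `best_accuracy` (verified by a
#'   fresh LOOCV recomputation at finalisation), `best_size`,
#'   `generations_run`, a per-generation `history` tibble (generation, r,
#'   best accuracy/size in the generation, hall-of-fame accuracy/size,
#'   cache counters), the seed and the effective config. Supports
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot].
#'
#' @examples
#' sim <- simulate_expression(n_samples = 24, n_attributes = 40,
#'                            n_informative = 3, effect_size = 3, seed = 2)
#' fit <- gsp(sim$dataset,
#'            config = gsp_config(pop_size = 10, max_generations = 5,
#'                                head_size = 4, seed = 2,
#'                                classifier = classifier_spec("nearest_centroid")))
#' glance(fit)
#' @export
gsp <- function(data, label_column = "class", config = gsp_config(),
                verbose = FALSE) {
  ds <- as_expression_dataset(data, label_column = label_column)
  if (n_samples(ds) < 3) stop_input("need at least 3 samples for leave-one-out evaluation")
  clash <- intersect(attribute_names(ds), config$fset$symbols)
  if (length(clash)) {
    stop_input(sprintf("attribute names collide with function symbols: %s",
                       paste(clash, collapse = ", ")))
  }

  with_seed(config$seed, {
    weights <- rank_attributes(ds, method = config$discretization)
    uniform_fallback <- !any(weights$eligible)
    if (uniform_fallback) {
      warn("all Information-Gain ranks are zero; falling back to uniform terminal sampling")
    }
    shape <- gene_shape(config$head_size, config$fset)
    population <- initialize_population(config$pop_size, shape,
                                        config$genes_per_chromosome, weights,
                                        uniform_fallback = uniform_fallback)
    cache <- fitness_cache()
    hof <- NULL
    stall <- 0L
    gen <- 0L
    history <- list()

    repeat {
      r <- runif(1, 0.1, 1)
      evaluator <- make_evaluator(ds, r, config$classifier, cache)
      records <- lapply(population, evaluator)
      acc <- vapply(records, function(x) x$accuracy, numeric(1))
      size <- vapply(records, function(x) x$subset_size, numeric(1))
      best_i <- order(-acc, size)[1]
      improved <- hof_better(acc[best_i], size[best_i], hof)
      if (improved) {
        hof <- list(accuracy = acc[best_i], size = size[best_i],
                    subset = records[[best_i]]$subset, generation = gen)
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history[[gen + 1L]] <- tibble(
        generation = gen, r = r,
        gen_best_accuracy = acc[best_i], gen_best_size = size[best_i],
        hof_accuracy = hof$accuracy, hof_size = hof$size,
        cache_hits = cache$hits, evaluations = cache$evaluations,
        trainings = cache$trainings
      )
      if (verbose) {
        message(sprintf("gen %d: r = %.3f best AC = %.4f s = %d (hof AC = %.4f s = %d)",
                        gen, r, acc[best_i], size[best_i], hof$accuracy, hof$size))
      }
      if (stop_condition(gen, stall, config)) break
      population <- next_generation(population, records, weights, evaluator,
                                    config$rates, config$elitism,
                                    classic = config$classic)
      gen <- gen + 1L
    }

    # finalisation check: the reported accuracy must reproduce from scratch
    final_ac <- if (length(hof$subset)) {
      loocv_accuracy(ds, hof$subset, config$classifier)
    } else 0
    stopifnot(isTRUE(all.equal(final_ac, hof$accuracy)))

    structure(list(
      best_subset = hof$subset,
      best_accuracy = hof$accuracy,
      best_size = hof$size,
      best_generation = hof$generation,
      generations_run = gen,
      history = dplyr::bind_rows(history),
      seed = config$seed,
      config = config,
      weights = weights,
      counters = list(cache_hits = cache$hits,
                      distinct_subsets = cache$evaluations,
                      classifier_trainings = cache$trainings),
      n_samples = n_samples(ds),
      n_attributes = n_attributes(ds)
    ), class = "gsp_result")
  })
}

#' @rdname gsp
#' @export
run_gsp <- function(data, config = gsp_config(), label_column = "class",
                    verbose = FALSE) {
  gsp(data, label_column = label_column, config = config, verbose = verbose)
}

#' @export
print.gsp_result <- function(x, ...) {
  cat(sprintf("<gsp_result> %d attributes selected from %d (LOOCV accuracy %.4f)\n",
              x$best_size, x$n_attributes, x$best_accuracy))
  cat(sprintf(" generations run: %d (best found at %d), seed %d\n",
              x$generations_run, x$best_generation, x$seed))
  cat(" subset:", paste(x$best_subset, collapse = ", "), "\n")
  invisible(x)
}
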