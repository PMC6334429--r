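#' Genetic operator rates and retry caps
#'
#' Default probabilities follow the selection runs' parameterisation:
#' mutation 0.044 per chromosome and recombination 0.3 per selected pair.
#' Both guided operators are accept-if-better and retry a bounded number of
#' times before returning their input unchanged, which guarantees
#' termination.
#'
#' @param mutation_rate Probability a chromosome is mutated.
#' @param recombination_rate Probability a selected pair recombines.
#' @param mutation_retries Proposal attempts per mutation call.
#' @param recombination_retries Gene-swap attempts per recombination call;
#'   `NULL` means "one per gene of the chromosome".
#' @return An `operator_rates` list.
#' @export
operator_rates <- function(mutation_rate = 0.044, recombination_rate = 0.3,
                           mutation_retries = 3L, recombination_retries = NULL) {
  if (mutation_rate < 0 || mutation_rate > 1 ||
      recombination_rate < 0 || recombination_rate > 1) {
    stop_input("rates must lie in [0, 1]")
  }
  if (mutation_retries < 1) stop_input("mutation_retries must be >= 1")
  if (!is.null(recombination_retries) && recombination_retries < 1) {
    stop_input("recombination_retries must be >= 1")
  }
  structure(list(mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 mutation_retries = as.integer(mutation_retries),
                 recombination_retries = recombination_retries),
            class = "operator_rates")
}

# fast name -> weight lookup vector from an attribute_weights table
weight_lookup <- function(weights) {
  setNames(weights$weight, weights$attribute)
}

#' Initialize a population of chromosomes
#'
#' Creates `pop_size` chromosomes whose terminal symbols are drawn by
#' roulette-wheel selection over the attribute weights, so class-informative
#' attributes dominate the initial terminal pool while zero-gain attributes
#' never enter it.
#'
#' @param pop_size Number of chromosomes (>= 2).
#' @param shape A [gene_shape()].
#' @param n_genes Genes per chromosome.
#' @param weights An `attribute_weights` table from [rank_attributes()].
#' @param root_function Force a function at each gene's first position.
#' @param uniform_fallback Sample uniformly over all attributes when every
#'   rank is zero (pathological input) instead of erroring.
#' @return A list of `gep_chromosome`s.
#' @export
initialize_population <- function(pop_size, shape, n_genes, weights,
                                  root_function = TRUE, uniform_fallback = FALSE) {
  if (pop_size < 2) stop_input("pop_size must be >= 2")
  sampler <- make_terminal_sampler(weights, uniform_fallback)
  lapply(seq_len(pop_size), function(i) {
    random_chromosome(shape, n_genes, sampler, root_function = root_function)
  })
}

# positions (gene index, symbol index) of expressed terminals of a chromosome
expressed_terminal_positions <- function(chromosome) {
  fset <- chromosome$shape$fset
  out <- list()
  for (gi in seq_along(chromosome$genes)) {
    g <- chromosome$genes[[gi]]
    k <- expressed_length(g$symbols, fset)
    syms <- g$symbols[seq_len(k)]
    idx <- which(!is_function_symbol(syms, fset))
    if (length(idx)) {
      out[[length(out) + 1L]] <- data.frame(gene = gi, pos = idx,
                                            symbol = syms[idx],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(data.frame(gene = integer(), pos = integer(),
                                          symbol = character()))
  do.call(rbind, out)
}

replace_symbol <- function(chromosome, gene_idx, pos, symbol) {
  chromosome$genes[[gene_idx]]$symbols[pos] <- symbol
  chromosome
}

#' Weight-guided mutation
#'
#' Locates the expressed terminal with the lowest attribute weight (ties:
#' lowest position), proposes a replacement — a function symbol or a
#' higher-weight terminal when the target sits in the head, a higher-weight
#' terminal only when it sits in the tail — and accepts the mutant only if
#' its fitness strictly exceeds the original's under the shared `r`.
#' Otherwise it retries up to `rates$mutation_retries` fresh proposals and
#' finally returns the chromosome unchanged. Fitness therefore never
#' decreases through mutation.
#'
#' `classic = TRUE` gives unguided GEP mutation instead: a uniformly random
#' position is replaced by a uniformly random legal symbol, with no fitness
#' gate (used for ablation runs).
#'
#' @param chromosome An evaluated `gep_chromosome`.
#' @param weights `attribute_weights` table.
#' @param evaluator Function `f(chromosome) -> fitness_record` sharing the
#'   generation's `r` (see [evaluate_chromosome()]).
#' @param rates An [operator_rates()].
#' @param record Optional `fitness_record` of `chromosome` (recomputed via
#'   `evaluator` when `NULL`).
#' @param classic Use unguided classic-GEP mutation.
#' @return The mutated (or original) `gep_chromosome`.
#' @export
mutate_chromosome <- function(chromosome, weights, evaluator, rates = operator_rates(),
                              record = NULL, classic = FALSE) {
  if (classic) return(classic_mutation(chromosome, weights))
  w <- weight_lookup(weights)
  terms <- expressed_terminal_positions(chromosome)
  if (nrow(terms) == 0) return(chromosome)
  tw <- unname(w[terms$symbol])
  tw[is.na(tw)] <- 0
  lt_row <- which.min(tw)  # ties -> lowest gene/position index (first match)
  lt <- terms[lt_row, ]
  lt_weight <- tw[lt_row]
  in_head <- lt$pos <= chromosome$shape$head_size

  higher <- weights[weights$weight > lt_weight & weights$eligible, ]
  fs <- chromosome$shape$fset$symbols
  if (!in_head && nrow(higher) == 0) return(chromosome)  # no legal move

  if (is.null(record)) record <- evaluator(chromosome)
  for (attempt in seq_len(rates$mutation_retries)) {
    use_function <- in_head && (nrow(higher) == 0 || runif(1) < 0.5)
    new_symbol <- if (use_function) {
      fs[sample.int(length(fs), 1L)]
    } else {
      higher$attribute[sample.int(nrow(higher), 1L, prob = higher$weight)]
    }
    if (identical(new_symbol, lt$symbol)) next
    candidate <- replace_symbol(chromosome, lt$gene, lt$pos, new_symbol)
    if (evaluator(candidate)$fitness > record$fitness) return(candidate)
  }
  chromosome
}

classic_mutation <- function(chromosome, weights) {
  shape <- chromosome$shape
  gi <- sample.int(length(chromosome$genes), 1L)
  pos <- sample.int(shape$length, 1L)
  fs <- shape$fset$symbols
  attrs <- weights$attribute
  in_head <- pos <= shape$head_size
  pick_fun <- in_head && pos > 1L && runif(1) < 0.5
  new_symbol <- if (pick_fun || (pos == 1L && runif(1) < 0.5)) {
    fs[sample.int(length(fs), 1L)]
  } else {
    attrs[sample.int(length(attrs), 1L)]
  }
  replace_symbol(chromosome, gi, pos, new_symbol)
}

#' Weight summation of a gene
#'
#' Sum of the attribute weights of a gene's expressed terminals, counted
#' with multiplicity. Recombination uses it to identify each chromosome's
#' "strong" (highest-sum) and "weak" (lowest-sum) genes.
#'
#' @param gene A `gep_gene`.
#' @param weights `attribute_weights` table.
#' @param distinct Count each distinct terminal once instead.
#' @return Non-negative numeric.
#' @export
gene_weight_sum <- function(gene, weights, distinct = FALSE) {
  terms <- gene_terminals(gene)
  if (distinct) terms <- unique(terms)
  if (length(terms) == 0) return(0)
  w <- weight_lookup(weights)[terms]
  sum(w, na.rm = TRUE)
}

#' Fitness-guided gene recombination
#'
#' Orders the parents by fitness into `hc` (higher) and `lc` (lower), then
#' swaps `lc`'s strongest gene (highest [gene_weight_sum()]) into the slot
#' of `hc`'s weakest gene, producing candidate `hc'`. The swap is kept only
#' if `fitness(hc') > max(fitness(c1), fitness(c2))`; otherwise the next
#' strongest `lc` gene is tried, up to `rates$recombination_retries`
#' attempts (default: one per gene), after which the parents are returned
#' unchanged. A changed output therefore strictly dominates both parents.
#'
#' @param c1,c2 Evaluated `gep_chromosome`s of the same shape.
#' @param weights `attribute_weights` table.
#' @param evaluator Fitness evaluator sharing the generation's `r`.
#' @param rates An [operator_rates()].
#' @param records Optional list of the parents' `fitness_record`s.
#' @return List of two chromosomes (improved pair, or the parents).
#' @export
recombine_chromosomes <- function(c1, c2, weights, evaluator,
                                  rates = operator_rates(), records = NULL) {
  if (is.null(records)) records <- list(evaluator(c1), evaluator(c2))
  f1 <- records[[1]]$fitness
  f2 <- records[[2]]$fitness
  if (f1 >= f2) {
    hc <- c1; lc <- c2; f_hc <- f1
  } else {
    hc <- c2; lc <- c1; f_hc <- f2
  }
  n_genes <- length(hc$genes)
  sums_hc <- vapply(hc$genes, gene_weight_sum, numeric(1), weights = weights)
  sums_lc <- vapply(lc$genes, gene_weight_sum, numeric(1), weights = weights)
  weak_slot <- which.min(sums_hc)
  donors <- order(sums_lc, decreasing = TRUE)
  max_tries <- min(rates$recombination_retries %||% n_genes, n_genes)
  f_best <- max(f1, f2)
  for (d in donors[seq_len(max_tries)]) {
    hc2 <- hc
    hc2$genes[[weak_slot]] <- lc$genes[[d]]
    if (evaluator(hc2)$fitness > f_best) {
      lc2 <- lc
      lc2$genes[[d]] <- hc$genes[[weak_slot]]
      return(if (f1 >= f2) list(hc2, lc2) else list(lc2, hc2))
    }
  }
  list(c1, c2)
}

#' Classic one-point short-sequence recombination
#'
#' Unguided exchange of a contiguous symbol span at the same position of the
#' same gene in both parents. Because head positions swap with head
#' positions and tail with tail, the children always satisfy the head/tail
#' rules. Used in classic-GEP ablation mode.
#'
#' @param c1,c2 `gep_chromosome`s of identical shape and gene count.
#' @return List of the two children.
#' @export
short_sequence_recombination <- function(c1, c2) {
  if (!identical(c1$shape$length, c2$shape$length) ||
      length(c1$genes) != length(c2$genes)) {
    stop_input("parents must share shape and gene count")
  }
  gi <- sample.int(length(c1$genes), 1L)
  len <- c1$shape$length
  start <- sample.int(len, 1L)
  span <- sample.int(len - start + 1L, 1L) - 1L  # span length 0 allowed
  if (span == 0) return(list(c1, c2))
  idx <- start:(start + span - 1L)
  g1 <- c1$genes[[gi]]$symbols
  g2 <- c2$genes[[gi]]$symbols
  tmp <- g1[idx]
  g1[idx] <- g2[idx]
  g2[idx] <- tmp
  c1$genes[[gi]]$symbols <- g1
  c2$genes[[gi]]$symbols <- g2
  list(c1, c2)
}

#' Produce the next generation
#'
#' Standard generational loop with elitism: the best `elitism` chromosomes
#' (by fitness, ties to the smaller subset) are copied unchanged, and the
#' remaining slots are filled by fitness-proportionate (roulette) parent
#' selection. Selected pairs recombine with probability
#' `rates$recombination_rate` (guided, [recombine_chromosomes()]) and each
#' resulting chromosome mutates with probability `rates$mutation_rate`
#' (guided, [mutate_chromosome()]). Population size is preserved.
#'
#' @param population List of `gep_chromosome`s.
#' @param records List of their `fitness_record`s (same order).
#' @param weights `attribute_weights` table.
#' @param evaluator Fitness evaluator sharing the generation's `r`.
#' @param rates An [operator_rates()].
#' @param elitism Number of elites copied unchanged.
#' @param classic Use unguided classic-GEP operators.
#' @return List of chromosomes of the same length as `population`.
#' @export
next_generation <- function(population, records, weights, evaluator,
                            rates = operator_rates(), elitism = 1L,
                            classic = FALSE) {
  pop_size <- length(population)
  stopifnot(length(records) == pop_size)
  fit <- vapply(records, function(rec) rec$fitness, numeric(1))
  size <- vapply(records, function(rec) rec$subset_size, numeric(1))
  elite_idx <- head(order(-fit, size), elitism)
  out <- population[elite_idx]

  probs <- if (sum(fit) > 0) fit / sum(fit) else rep(1 / pop_size, pop_size)
  pick_parent <- function() sample.int(pop_size, 1L, prob = probs)

  while (length(out) < pop_size) {
    i <- pick_parent()
    if (length(out) <= pop_size - 2L) {
      j <- pick_parent()
      pair <- list(population[[i]], population[[j]])
      if (runif(1) < rates$recombination_rate) {
        pair <- if (classic) {
          short_sequence_recombination(pair[[1]], pair[[2]])
        } else {
          recombine_chromosomes(pair[[1]], pair[[2]], weights, evaluator,
                                rates, records = list(records[[i]], records[[j]]))
        }
      }
      children <- pair
    } else {
      children <- list(population[[i]])
    }
    for (ch in children) {
      if (runif(1) < rates$mutation_rate) {
        ch <- mutate_chromosome(ch, weights, evaluator, rates, classic = classic)
      }
      out[[length(out) + 1L]] <- ch
    }
  }
  out[seq_len(pop_size)]
}
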