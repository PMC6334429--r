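test_that("initial populations are valid, sized, and dominated by heavy attributes", {
  w <- toy_weights(c(5, 4, 3, 0.1, 0.1, 0, 0), paste0("a", 1:7))
  sh <- gene_shape(4)
  set.seed(2)
  pop <- initialize_population(20, sh, n_genes = 2, weights = w)
  expect_length(pop, 20)
  for (ch in pop) {
    expect_true(isTRUE(validate_chromosome(ch, attributes = w$attribute, n_genes = 2)))
  }
  # ineligible attributes never appear; heavy attributes dominate terminals
  terms <- unlist(lapply(pop, function(ch) {
    unlist(lapply(ch$genes, function(g) {
      g$symbols[!gspr:::is_function_symbol(g$symbols, sh$fset)]
    }))
  }))
  expect_false(any(terms %in% c("a6", "a7")))
  expect_gte(mean(terms %in% c("a1", "a2", "a3")), 0.8)

  expect_error(initialize_population(1, sh, 1, w), class = "gspr_input_error")
})

test_that("guided mutation targets the weakest expressed terminal and never regresses", {
  # the worked head-3 scenario: lowest-weight expressed terminal is replaced
  w <- toy_weights(c(0.05, 0.3, 0.25, 0.4), c("a1", "a2", "a5", "a9"))
  sh <- gene_shape(3)
  ch <- gspr:::new_chromosome(list(gspr:::new_gene(
    c("+", "a9", "a1", "a2", "a5", "a2", "a9"), sh)), sh)
  ev <- stub_evaluator(w, r = 0.5, t_total = 4)
  set.seed(6)
  out <- mutate_chromosome(ch, w, ev, operator_rates(mutation_retries = 20))
  expect_true(isTRUE(validate_chromosome(out)))
  # a1 (the weakest expressed terminal, head position 3) was replaced
  expect_false("a1" %in% selected_attributes(out))
  expect_gt(ev(out)$fitness, ev(ch)$fitness)
})

test_that("mutation with no legal move returns the chromosome unchanged", {
  # lt sits in the tail and no terminal has a higher weight
  w <- toy_weights(c(1, 1), c("a1", "a2"))  # equal weights: none strictly higher
  sh <- gene_shape(2)
  ch <- gspr:::new_chromosome(list(gspr:::new_gene(
    c("Q", "Q", "a1", "a2", "a2"), sh)), sh)
  ev <- stub_evaluator(w)
  set.seed(1)
  out <- mutate_chromosome(ch, w, ev)
  expect_identical(karva_string(out), karva_string(ch))
})

test_that("gene weight sums count expressed terminals with multiplicity", {
  w <- toy_weights(c(2, 1, 1), c("a2", "a1", "a3"))  # weights 0.5, 0.25, 0.25
  sh <- gene_shape(2)
  g <- gspr:::new_gene(c("+", "a2", "a1", "a1", "a1"), sh)
  expect_equal(gene_weight_sum(g, w), 0.75)
  g2 <- gspr:::new_gene(c("+", "a2", "a2", "a1", "a1"), sh)
  expect_equal(gene_weight_sum(g2, w), 1.0)                      # a2 counted twice
  expect_equal(gene_weight_sum(g2, w, distinct = TRUE), 0.5)
  zero <- toy_weights(c(0, 0, 1), c("a1", "a2", "a3"))
  expect_equal(gene_weight_sum(g, zero), 0)
})

test_that("guided recombination swaps the strong donor gene into the weak slot", {
  w <- toy_weights(c(10, 8, 1, 1), c("a1", "a2", "a3", "a4"))
  sh <- gene_shape(2)
  strong1 <- gspr:::new_gene(c("+", "a1", "a2", "a1", "a2"), sh)
  weak1 <- gspr:::new_gene(c("+", "a3", "a4", "a3", "a4"), sh)
  strong2 <- gspr:::new_gene(c("+", "a2", "a1", "a2", "a1"), sh)
  weak2 <- gspr:::new_gene(c("+", "a4", "a3", "a4", "a3"), sh)
  c1 <- gspr:::new_chromosome(list(strong1, weak1), sh)   # will be hc
  c2 <- gspr:::new_chromosome(list(weak2, strong2), sh)   # lc: strong gene second
  ev <- stub_evaluator(w, r = 0.5, t_total = 4)
  out <- recombine_chromosomes(c1, c2, w, ev)
  f_out <- vapply(out, function(ch) ev(ch)$fitness, numeric(1))
  f_par <- c(ev(c1)$fitness, ev(c2)$fitness)
  changed <- !identical(karva_string(out[[1]]), karva_string(c1)) ||
    !identical(karva_string(out[[2]]), karva_string(c2))
  if (changed) {
    # the improved child replaced c1's weak gene with c2's strong gene
    expect_gt(max(f_out), max(f_par))
  }
  for (ch in out) expect_true(isTRUE(validate_chromosome(ch)))
})

test_that("single-gene chromosomes recombine wholesale or not at all", {
  w <- toy_weights(c(3, 1), c("a1", "a2"))
  sh <- gene_shape(2)
  c1 <- gspr:::new_chromosome(list(gspr:::new_gene(c("+", "a1", "a1", "a1", "a1"), sh)), sh)
  c2 <- gspr:::new_chromosome(list(gspr:::new_gene(c("+", "a2", "a2", "a2", "a2"), sh)), sh)
  ev <- stub_evaluator(w)
  out <- recombine_chromosomes(c1, c2, w, ev)
  ks <- sort(c(karva_string(out[[1]]), karva_string(out[[2]])))
  expect_true(identical(ks, sort(c(karva_string(c1), karva_string(c2)))))
})

test_that("classic short-sequence recombination swaps aligned spans and stays legal", {
  w <- toy_weights(rep(1, 4), paste0("a", 1:4))
  sampler <- gspr:::make_terminal_sampler(w)
  set.seed(12)
  for (i in 1:200) {
    sh <- gene_shape(sample(2:5, 1))
    c1 <- random_chromosome(sh, 2, sampler)
    c2 <- random_chromosome(sh, 2, sampler)
    out <- short_sequence_recombination(c1, c2)
    expect_true(isTRUE(validate_chromosome(out[[1]])))
    expect_true(isTRUE(validate_chromosome(out[[2]])))
    # symbol multiset is conserved across the pair
    all_before <- sort(c(unlist(lapply(c1$genes, `[[`, "symbols")),
                         unlist(lapply(c2$genes, `[[`, "symbols"))))
    all_after <- sort(c(unlist(lapply(out[[1]]$genes, `[[`, "symbols")),
                        unlist(lapply(out[[2]]$genes, `[[`, "symbols"))))
    expect_identical(all_after, all_before)
  }
})

test_that("next generation preserves size and carries the elite unchanged", {
  w <- toy_weights(c(4, 3, 2, 1), paste0("a", 1:4))
  sh <- gene_shape(3)
  sampler <- gspr:::make_terminal_sampler(w)
  ev <- stub_evaluator(w, r = 0.5, t_total = 4)
  set.seed(33)
  pop <- initialize_population(12, sh, 2, w)
  records <- lapply(pop, ev)
  fit <- vapply(records, `[[`, numeric(1), "fitness")
  best <- karva_string(pop[[order(-fit)[1]]])
  nxt <- next_generation(pop, records, w, ev, operator_rates(), elitism = 1)
  expect_length(nxt, 12)
  expect_true(best %in% vapply(nxt, karva_string, character(1)))
  for (ch in nxt) expect_true(isTRUE(validate_chromosome(ch)))

  # zero rates: pure resampling of parents
  none <- next_generation(pop, records, w, ev,
                          operator_rates(mutation_rate = 0, recombination_rate = 0))
  parents <- vapply(pop, karva_string, character(1))
  expect_true(all(vapply(none, karva_string, character(1)) %in% parents))
})
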